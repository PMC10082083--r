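#' Simulate a complete synthetic methylome study
#'
#' Runs the whole generator: genome and annotation, true methylation states
#' with planted ground truth, bisulfite counts with lambda spike-in,
#' expression table and sRNA tracks. With `outdir` set, all on-disk formats
#' are written: genome FASTA, gene models as GFF3, TEs as BED, one cytosine
#' report per sample, one lambda report per sample, TPM table, sample sheet,
#' sRNA bedGraphs and the ground truth as JSON.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return invisible list with `genome`, `annotation`, `states`, `counts`
#'   (samples + lambda), `expression`, `srna` and `sample_sheet`.
#' @export
simulate_methylome <- function(config, outdir = NULL) {
  gen <- generate_genome(config)
  states <- simulate_methylation_states(gen$genome, gen$annotation, config)
  counts <- simulate_bs_counts(states, config)
  expr <- simulate_expression(gen$annotation, states, config)
  srna <- simulate_srna_tracks(states, config)
  res <- list(genome = gen$genome, annotation = gen$annotation, states = states,
              counts = counts, expression = expr, srna = srna,
              sample_sheet = states$sample_sheet)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(gen$genome, file.path(outdir, "genome.fa"))
    write_gff3(gen$annotation, file.path(outdir, "genes.gff3"))
    if (nrow(gen$annotation$tes))
      write_bed(gen$annotation$tes[, .(chrom, start, end, name = te_id,
                                       score = 0, strand = "+")],
                file.path(outdir, "tes.bed"))
    for (sid in names(counts$samples)) {
      write_cytosine_report(counts$samples[[sid]],
                            file.path(outdir, paste0(sid, ".cytosine_report.tsv")))
      write_cytosine_report(counts$lambda[[sid]],
                            file.path(outdir, paste0(sid, ".lambda.tsv")))
    }
    write_tpm_table(expr, file.path(outdir, "tpm.tsv"))
    write_sample_sheet(states$sample_sheet, file.path(outdir, "samples.tsv"))
    for (cl in names(srna))
      write_bedgraph(srna[[cl]], file.path(outdir, paste0("srna_", cl, ".bedgraph")))
    write_ground_truth(states$ground_truth, file.path(outdir, "ground_truth.json"))
    write_config_yaml(config, file.path(outdir, "sim_config.yaml"))
  }
  invisible(res)
}
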