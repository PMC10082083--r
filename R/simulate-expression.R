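#' Simulate a TPM expression table coupled to methylation
#'
#' Log expression of each gene follows a linear coupling to its true
#' exon+downstream methylation (negative slope by default) plus log-normal
#' gene noise; per-sample values add small log-normal noise on top. A
#' configurable fraction of genes is silenced to TPM = 0, selected by a
#' noisy threshold on gene methylation so silenced genes occupy the
#' methylated extreme. Marker genes are overridden with their planted
#' strictly increasing per-age TPM series.
#'
#' @param annotation a [genome_annotation()].
#' @param states a [simulate_methylation_states()] result.
#' @param config a [sim_config()].
#' @return data.table with `gene_id` and one TPM column per sample.
#' @export
simulate_expression <- function(annotation, states, config) {
  stopifnot(inherits(states, "meth_states"))
  sheet <- states$sample_sheet
  gm <- states$gene_meth
  genes <- annotation$genes
  if (nrow(genes) == 0L) {
    out <- data.table(gene_id = character())
    for (sid in sheet$sample_id) out[, (sid) := numeric()]
    return(out[])
  }
  withr::with_seed(derive_seed(config$seed, 4L), {
    gm <- gm[match(genes$gene_id, gene_id)]
    latent <- config$expr_intercept + config$expr_slope * gm$true_meth +
      rnorm(nrow(gm), 0, config$expr_noise_sd)
    zero <- rep(FALSE, nrow(gm))
    if (config$zero_expr_fraction > 0) {
      ## silencing is thresholded on methylation itself (plus a little
      ## noise), so TPM = 0 genes sit at the methylated extreme while the
      ## weakly expressed groups stay populated by near-threshold genes
      zscore <- gm$true_meth + rnorm(nrow(gm), 0, 0.05)
      k <- min(nrow(gm), round(config$zero_expr_fraction * nrow(gm)))
      if (k > 0) zero[order(-zscore)[seq_len(k)]] <- TRUE
    }
    out <- data.table(gene_id = genes$gene_id)
    ages <- config$ages
    for (i in seq_len(nrow(sheet))) {
      sid <- sheet$sample_id[i]
      tpm <- exp(latent + rnorm(nrow(gm), 0, config$expr_sample_noise_sd))
      tpm[zero] <- 0
      if (any(genes$is_marker)) {
        a <- match(sheet$age_years[i], ages)
        tpm[genes$is_marker] <- config$marker_tpm[a] *
          exp(rnorm(sum(genes$is_marker), 0, config$marker_tpm_noise_sd))
      }
      out[, (sid) := round(tpm, 4)]
    }
    out[]
  })
}

#' Simulate small-RNA density tracks
#'
#' Generates binned density tracks for the 21-, 22- and 24-nt sRNA length
#' classes as log-normal noise with an optional log-linear coupling to the
#' true methylation level of each bin (`srna_coupling`, default 0 for every
#' class, i.e. independence).
#'
#' @param states a [simulate_methylation_states()] result.
#' @param config a [sim_config()].
#' @return named list (`"21nt"`, `"22nt"`, `"24nt"`) of bedGraph-style
#'   data.tables with columns chrom, start, end, score.
#' @export
simulate_srna_tracks <- function(states, config) {
  stopifnot(inherits(states, "meth_states"))
  bs <- as.integer(config$srna_bin_bp)
  sites <- states$sites
  pbar <- rowMeans(states$p)
  bins <- data.table(chrom = sites$chrom, bin_start = (sites$pos0 %/% bs) * bs,
                     p = pbar)[, .(meth = mean(p)), by = .(chrom, bin_start)]
  setorder(bins, chrom, bin_start)
  z <- as.vector(scale(bins$meth))
  if (all(is.na(z))) z <- rep(0, nrow(bins))
  withr::with_seed(derive_seed(config$seed, 5L), {
    out <- lapply(c("21", "22", "24"), function(cl) {
      cc <- config$srna_coupling[[cl]] %||% 0
      score <- exp(log(5) + cc * z + rnorm(nrow(bins), 0, 0.5))
      data.table(chrom = bins$chrom, start = bins$bin_start,
                 end = bins$bin_start + bs, score = round(score, 4))
    })
    names(out) <- paste0(c("21", "22", "24"), "nt")
    out
  })
}
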