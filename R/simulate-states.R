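#' Simulate true per-cytosine methylation states for an age series
#'
#' Every cytosine receives a true methylation probability from its feature
#' class (TE > exon > intron > intergenic priority) and context, modulated by
#' a per-gene factor on exons and 2-kb flanks (the handle that couples
#' methylation to expression) plus optional site-level jitter shared by all
#' samples. On top of this background the generator plants, on the 1000-bp
#' DMR grid: age-trend bins whose level moves linearly over the age index
#' from a start level to start +/- effect (hyper/hypo), age-independent bins
#' in which the two replicates of every age differ by a fixed offset, and
#' marker-gene segments whose CHG level strictly decreases with age.
#'
#' @param genome chromosome sequences (DNAStringSet or named character).
#' @param annotation a [genome_annotation()].
#' @param config a [sim_config()].
#' @return an object of class `meth_states`: list with `sites` (per-cytosine
#'   table with feature class), `p` (sites x samples matrix of true
#'   methylation probabilities), `sample_sheet`, `ground_truth`, `gene_meth`
#'   (per-gene factor and true exon+downstream methylation) and the
#'   originating `annotation` and `config`.
#' @export
simulate_methylation_states <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "genome_annotation"))
  sites <- classify_contexts(genome)
  sites[, pos0 := pos - 1L]

  sheet <- data.table(
    age_years = rep(config$ages, each = config$replicates_per_age),
    replicate = rep(seq_len(config$replicates_per_age), length(config$ages)))
  sheet[, sample_id := sprintf("age%02d_rep%d", age_years, replicate)]
  setcolorder(sheet, c("sample_id", "age_years", "replicate"))
  n_ages <- length(config$ages)

  withr::with_seed(derive_seed(config$seed, 2L), {
    ## ---- feature class (priority TE > exon > intron > intergenic) ------
    sites[, class := "intergenic"]
    intr <- introns(annotation)
    for (layer in list(list(intr, "intron"),
                       list(annotation$exons, "exon"),
                       list(annotation$tes, "TE"))) {
      if (nrow(layer[[1]])) {
        hit <- overlap_first(sites, layer[[1]])
        sites[!is.na(hit), class := layer[[2]]]
      }
    }

    ## ---- per-gene methylation factor on exons and flanks ---------------
    genes <- annotation$genes
    fac <- NULL
    if (nrow(genes)) {
      fac <- data.table(gene_id = genes$gene_id,
                        meth_factor = runif(nrow(genes),
                                            config$gene_meth_factor_range[1],
                                            config$gene_meth_factor_range[2]))
      fac[genes$is_marker, meth_factor := 1]
      flank <- 2000L    # matches the analysis-side flank width
      mod_iv <- rbindlist(list(
        annotation$exons[, .(gene_id, chrom, start, end)],
        gene_flanks(annotation, flank, "up")[, .(gene_id, chrom, start, end)],
        gene_flanks(annotation, flank, "down")[, .(gene_id, chrom, start, end)]))
      hit <- overlap_first(sites, mod_iv)
      sites[, gene_id := NA_character_]
      sites[!is.na(hit), gene_id := mod_iv$gene_id[hit[!is.na(hit)]]]
    } else sites[, gene_id := NA_character_]

    ## ---- background probability ----------------------------------------
    base_dt <- rbindlist(lapply(CONTEXTS, function(ctx)
      data.table(context = ctx,
                 class = names(config$base_levels[[ctx]]),
                 base_p = unname(config$base_levels[[ctx]]))))
    sites[base_dt, base_p := i.base_p, on = c("context", "class")]
    if (!is.null(fac)) {
      sites[fac, meth_factor := i.meth_factor, on = "gene_id"]
      sites[is.na(meth_factor), meth_factor := 1]
    } else sites[, meth_factor := 1]
    p0 <- clip01(sites$base_p * sites$meth_factor)
    if (config$level_jitter_sd > 0)
      p0 <- clip01(p0 + rnorm(length(p0), 0, config$level_jitter_sd))

    p <- matrix(p0, nrow = nrow(sites), ncol = nrow(sheet),
                dimnames = list(NULL, sheet$sample_id))

    ## ---- marker segments ------------------------------------------------
    marker_seg <- data.table(gene_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             context = character())
    if (nrow(genes) && any(genes$is_marker)) {
      mk <- genes[is_marker == TRUE]
      seg_len <- config$marker_upstream_bp + config$marker_intron_span_bp
      marker_seg <- mk[, .(
        gene_id, chrom,
        start = fifelse(strand == "+",
                        start - config$marker_upstream_bp,
                        end - (seg_len - config$marker_upstream_bp)),
        end = fifelse(strand == "+",
                      start + (seg_len - config$marker_upstream_bp),
                      end + config$marker_upstream_bp),
        context = "CHG")]
      marker_seg[, start := pmax(start, 0L)]
      hit <- overlap_first(sites, marker_seg)
      in_seg <- !is.na(hit) & sites$context == "CHG"
      for (a in seq_len(n_ages)) {
        cols <- sheet[age_years == config$ages[a], sample_id]
        p[in_seg, cols] <- config$marker_chg_levels[a]
      }
    }

    ## ---- eligible grid bins for planting --------------------------------
    bs <- 1000L
    sites[, bin_start := (pos0 %/% bs) * bs]
    bin_ctx <- sites[, .(n = .N), by = .(chrom, bin_start, context)]
    in_marker <- overlap_first(
      data.table(chrom = bin_ctx$chrom, pos0 = bin_ctx$bin_start + bs %/% 2L),
      marker_seg)
    bin_ctx[, eligible := n >= 8L & is.na(in_marker)]

    taken <- data.table(chrom = character(), bin_start = integer())
    pick_bins <- function(ctx, k) {
      cand <- bin_ctx[context == ctx & eligible == TRUE]
      cand <- cand[!taken, on = c("chrom", "bin_start")]
      if (nrow(cand) < k)
        stop(sprintf("not enough eligible %s bins to plant %d", ctx, k),
             call. = FALSE)
      sel <- cand[sample(.N, k), .(chrom, bin_start)]
      taken <<- rbind(taken, sel)
      sel
    }

    planted <- list()
    lev_cols <- paste0("level_", config$ages, "y")
    for (ctx in CONTEXTS) {
      for (dir in c("hyper", "hypo")) {
        k <- config$n_planted_age_dmrs[[ctx]][[dir]] %||% 0L
        if (k <= 0L) next
        sel <- pick_bins(ctx, k)
        lev <- config$planted_base_level +
          config$planted_effect * (seq_len(n_ages) - 1) / (n_ages - 1)
        if (dir == "hypo") lev <- rev(lev)
        idx <- sites[sel, on = c("chrom", "bin_start"), which = TRUE]
        idx <- idx[sites$context[idx] == ctx]
        for (a in seq_len(n_ages)) {
          cols <- sheet[age_years == config$ages[a], sample_id]
          p[idx, cols] <- lev[a]
        }
        gt <- copy(sel)[, `:=`(context = ctx, direction = dir)]
        for (a in seq_len(n_ages)) gt[, (lev_cols[a]) := lev[a]]
        planted[[length(planted) + 1L]] <- gt
      }
    }
    planted <- if (length(planted)) rbindlist(planted) else
      data.table(chrom = character(), bin_start = integer(),
                 context = character(), direction = character())

    ## ---- replicate-variable bins ----------------------------------------
    repvar <- data.table(chrom = character(), bin_start = integer())
    if (config$n_replicate_variable_bins > 0L) {
      repvar <- pick_bins("CG", config$n_replicate_variable_bins)
      idx <- sites[repvar, on = c("chrom", "bin_start"), which = TRUE]
      r1 <- sheet[replicate == 1L, sample_id]
      r2 <- sheet[replicate != 1L, sample_id]
      p[idx, r1] <- config$replicate_bin_level
      p[idx, r2] <- config$replicate_bin_level + config$replicate_bin_offset
    }

    ## ---- per-gene true exon+downstream methylation ----------------------
    gene_meth <- data.table(gene_id = character(), meth_factor = numeric(),
                            true_meth = numeric())
    if (nrow(genes)) {
      reg <- rbindlist(list(
        annotation$exons[, .(gene_id, chrom, start, end)],
        gene_flanks(annotation, 2000L, "down")[, .(gene_id, chrom, start, end)]))
      hit <- overlap_first(sites, reg)
      keep <- !is.na(hit) & sites$context %in% c("CG", "CHG")
      gm <- data.table(gene_id = reg$gene_id[hit[keep]], pbar = p0[keep])
      gm <- gm[, .(true_meth = mean(pbar)), by = gene_id]
      gene_meth <- merge(fac, gm, by = "gene_id", all.x = TRUE)
      gene_meth[is.na(true_meth), true_meth := mean(gm$true_meth)]
    }

    gt_markers <- marker_seg
    if (nrow(gt_markers)) {
      for (a in seq_len(n_ages)) gt_markers[, (lev_cols[a]) := config$marker_chg_levels[a]]
      for (a in seq_len(n_ages))
        gt_markers[, (paste0("tpm_", config$ages[a], "y")) := config$marker_tpm[a]]
    }

    sites[, c("base_p", "meth_factor", "bin_start") := NULL]
    structure(list(
      sites = sites[], p = p, sample_sheet = sheet,
      ground_truth = list(planted_dmr_bins = planted,
                          replicate_variable_bins = repvar,
                          marker_segments = gt_markers),
      gene_meth = gene_meth, annotation = annotation, config = config),
      class = "meth_states")
  })
}

#' @export
print.meth_states <- function(x, ...) {
  cat(sprintf(
    "meth_states: %d cytosines x %d samples; %d planted age bins, %d replicate bins, %d markers\n",
    nrow(x$sites), ncol(x$p), nrow(x$ground_truth$planted_dmr_bins),
    nrow(x$ground_truth$replicate_variable_bins),
    nrow(x$ground_truth$marker_segments)))
  invisible(x)
}
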