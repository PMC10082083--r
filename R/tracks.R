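## Binned genome-wide statistics: replicate correlation, chromosome tracks,
## sRNA-methylation correlation.

bin_levels <- function(levels, bin_size, by_context = TRUE) {
  lv <- copy(levels)[, bin_start := ((pos - 1L) %/% as.integer(bin_size)) *
                       as.integer(bin_size)]
  keys <- if (by_context) c("chrom", "bin_start", "context") else
    c("chrom", "bin_start")
  lv[, .(m = sum(as.numeric(count_m)), cov = sum(as.numeric(count_m + count_u)),
         n_sites = .N), by = keys]
}

#' Pearson correlation between two replicates over genome bins
#'
#' The genome is split into fixed bins (default 5 kb); each replicate's
#' count-weighted methylation level is computed per bin, bins lacking
#' covered sites in either replicate are dropped, and the Pearson
#' correlation over the remaining bins is reported per context and for all
#' contexts combined.
#'
#' @param levels_a,levels_b [site_levels()] tables of the two replicates.
#' @param config a [pipeline_config()] (`bin_size_corr` sets the bin width).
#' @return data.table with `context` (including `"combined"`), `n_bins`,
#'   `pearson_r` (NA with fewer than 3 shared bins).
#' @export
replicate_correlation <- function(levels_a, levels_b, config = pipeline_config()) {
  one <- function(ctx) {
    la <- if (is.null(ctx)) levels_a else levels_a[context == ctx]
    lb <- if (is.null(ctx)) levels_b else levels_b[context == ctx]
    ba <- bin_levels(la, config$bin_size_corr, by_context = FALSE)
    bb <- bin_levels(lb, config$bin_size_corr, by_context = FALSE)
    mg <- merge(ba, bb, by = c("chrom", "bin_start"), suffixes = c("_a", "_b"))
    mg <- mg[cov_a > 0 & cov_b > 0]
    r <- if (nrow(mg) < 3L) NA_real_ else cor(mg$m_a / mg$cov_a, mg$m_b / mg$cov_b)
    data.table(context = ctx %||% "combined", n_bins = nrow(mg), pearson_r = r)
  }
  rbindlist(lapply(list("CG", "CHG", "CHH", NULL), one))
}

#' Chromosome-scale binned tracks
#'
#' Per fixed genome bin (20 Mb in the full-scale study; configurable for
#' compact genomes): count-weighted methylation level per context and per
#' trinucleotide sub-context (4 CG + 3 CHG + 9 CHH series), repeat coverage
#' fraction, gene density, and optional sRNA density per length class.
#' Bins at chromosome ends may be short and are flagged.
#'
#' @param levels a [site_levels()] table.
#' @param annotation a [genome_annotation()].
#' @param srna_tracks optional named list of bedGraph data.tables.
#' @param bin_size bin width in bp; defaults to `config$chrom_track_bin`.
#' @param config a [pipeline_config()].
#' @return list with `methylation` (rows per bin x context x sub-context,
#'   where `subcontext == "all"` aggregates the context), `features` and
#'   `srna` data.tables.
#' @export
chromosome_tracks <- function(levels, annotation, srna_tracks = NULL,
                              bin_size = NULL, config = pipeline_config()) {
  bs <- as.integer(bin_size %||% config$chrom_track_bin)
  grid <- rbindlist(lapply(names(annotation$chrom_lengths), function(ch)
    data.table(chrom = ch,
               bin_start = seq(0L, max(0L, as.integer(annotation$chrom_lengths[[ch]]) - 1L),
                               by = bs))))
  grid[, end := pmin(bin_start + bs, as.integer(annotation$chrom_lengths[chrom]))]
  grid[, width := end - bin_start]
  grid[, short := width < bs]

  lv <- copy(levels)[, bin_start := ((pos - 1L) %/% bs) * bs]
  meth_sub <- lv[, .(level = weighted_level(count_m, count_u), n_sites = .N),
                 by = .(chrom, bin_start, context, subcontext)]
  meth_ctx <- lv[, .(subcontext = "all", level = weighted_level(count_m, count_u),
                     n_sites = .N), by = .(chrom, bin_start, context)]
  meth <- rbind(meth_ctx, meth_sub, use.names = TRUE)
  setorder(meth, chrom, bin_start, context, subcontext)

  feat <- copy(grid)
  feat[, gene_density := 0]
  feat[, repeat_fraction := 0]
  if (nrow(annotation$genes)) {
    gmid <- annotation$genes[, .(chrom, pos0 = as.integer((start + end) / 2))]
    gmid[, bin_start := (pos0 %/% bs) * bs]
    gcnt <- gmid[, .N, by = .(chrom, bin_start)]
    feat[gcnt, gene_density := i.N, on = c("chrom", "bin_start")]
  }
  if (nrow(annotation$tes)) {
    te <- annotation$tes
    pieces <- rbindlist(lapply(seq_len(nrow(feat)), function(i) {
      x <- te[chrom == feat$chrom[i] & start < feat$end[i] & end > feat$bin_start[i]]
      if (nrow(x) == 0L) return(NULL)
      data.table(idx = i, bases = sum(pmin(x$end, feat$end[i]) -
                                        pmax(x$start, feat$bin_start[i])))
    }))
    if (!is.null(pieces) && nrow(pieces))
      feat[pieces$idx, repeat_fraction := pieces$bases / width]
  }

  srna <- NULL
  if (!is.null(srna_tracks)) {
    srna <- rbindlist(lapply(names(srna_tracks), function(cl) {
      tr <- srna_tracks[[cl]]
      x <- copy(tr)[, bin_start := (start %/% bs) * bs]
      x[, .(length_class = cl, density = mean(score)), by = .(chrom, bin_start)]
    }))
  }
  list(methylation = meth[],
       features = feat[, .(chrom, bin_start, end, width, short,
                           gene_density, repeat_fraction)],
       srna = srna)
}

#' Correlation between an sRNA density track and methylation
#'
#' Bins the methylation levels on the sRNA track's grid and reports Pearson
#' and Spearman correlations (with p-values) per context; `NA` when the
#' track is constant or fewer than 3 bins are shared.
#'
#' @param srna_track bedGraph data.table (`chrom`, `start`, `end`, `score`).
#' @param levels a [site_levels()] table.
#' @param bin_size bin width matching the track resolution.
#' @return data.table with `context`, `n_bins`, `pearson_r`, `pearson_p`,
#'   `spearman_r`, `spearman_p`.
#' @export
track_methylation_correlation <- function(srna_track, levels, bin_size) {
  bs <- as.integer(bin_size)
  tr <- copy(srna_track)[, bin_start := (start %/% bs) * bs]
  tr <- tr[, .(density = mean(score)), by = .(chrom, bin_start)]
  one <- function(ctx) {
    lb <- bin_levels(if (is.null(ctx)) levels else levels[context == ctx],
                     bs, by_context = FALSE)
    mg <- merge(lb[cov > 0][, level := m / cov], tr, by = c("chrom", "bin_start"))
    if (nrow(mg) < 3L || sd(mg$density) == 0 || sd(mg$level) == 0)
      return(data.table(context = ctx %||% "combined", n_bins = nrow(mg),
                        pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_r = NA_real_, spearman_p = NA_real_))
    pe <- cor.test(mg$level, mg$density, method = "pearson")
    sp <- suppressWarnings(cor.test(mg$level, mg$density, method = "spearman"))
    data.table(context = ctx %||% "combined", n_bins = nrow(mg),
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_r = unname(sp$estimate), spearman_p = sp$p.value)
  }
  rbindlist(lapply(list("CG", "CHG", "CHH", NULL), one))
}
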