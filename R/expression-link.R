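#' Expression groups from a TPM table
#'
#' Genes are split into the five canonical groups TPM = 0, 0 < TPM <= 1,
#' 1 < TPM <= 10, 10 < TPM <= 50 and TPM > 50 (half-open on the left).
#' The grouping value is the mean TPM across samples, or a single sample's
#' TPM when `sample` is given.
#'
#' @param expr TPM table (`gene_id` + one column per sample).
#' @param config a [pipeline_config()] (`expression_breaks`).
#' @param sample optional sample id.
#' @return data.table with `gene_id`, `value`, `group` (ordered factor).
#' @export
expression_groups <- function(expr, config = pipeline_config(), sample = NULL) {
  scols <- setdiff(names(expr), "gene_id")
  if (!is.null(sample)) {
    if (!sample %in% scols) stop("unknown sample: ", sample, call. = FALSE)
    val <- expr[[sample]]
  } else {
    val <- rowMeans(as.matrix(expr[, ..scols]))
  }
  if (any(val < 0, na.rm = TRUE)) stop("negative TPM", call. = FALSE)
  br <- config$expression_breaks            # c(0, 1, 10, 50)
  labs <- c(sprintf("TPM=%g", br[1]),
            sprintf("%g<TPM<=%g", br[1], br[2]),
            sprintf("%g<TPM<=%g", br[2], br[3]),
            sprintf("%g<TPM<=%g", br[3], br[4]),
            sprintf("TPM>%g", br[4]))
  grp <- cut(val, breaks = c(-Inf, br, Inf), labels = labs,
             right = TRUE, ordered_result = TRUE)
  data.table(gene_id = expr$gene_id, value = val, group = grp)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Exact for small tie-free samples, normal approximation with continuity
#' and tie correction otherwise (the [stats::wilcox.test()] conventions).
#'
#' @param x,y numeric samples.
#' @return p-value.
#' @export
mann_whitney_p <- function(x, y) {
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: two groups share a letter if and only if
#' their pairwise p-value is at or above `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p-values (diagonal ignored).
#' @param alpha significance threshold.
#' @return character vector of letter codes, one per row of `pmat`.
#' @export
compact_letter_display <- function(pmat, alpha = 0.01) {
  k <- nrow(pmat)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      for (s in seq_along(sets)) {
        st <- sets[[s]]
        if (all(c(i, j) %in% st)) {
          sets[[s]] <- setdiff(st, i)
          sets[[length(sets) + 1L]] <- setdiff(st, j)
        }
      }
      ## absorb subsets
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) for (b in seq_along(sets))
        if (a != b && keep[a] && keep[b] &&
            all(sets[[a]] %in% sets[[b]]) && length(sets[[a]]) < length(sets[[b]]))
          keep[a] <- FALSE
      ## drop exact duplicates
      sets <- sets[keep]
      sets <- sets[!duplicated(lapply(sets, sort))]
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = ""), "")
  out
}

#' Region methylation compared across expression groups
#'
#' For every region class and context: group medians of per-gene levels,
#' all pairwise two-sided Mann-Whitney tests, and a compact letter display
#' at the configured threshold (raw p < 0.01 by default). Groups with
#' fewer than 2 genes are excluded and noted in the `excluded_groups`
#' attribute.
#'
#' @param region_meth a [region_methylation()] table.
#' @param groups an [expression_groups()] table.
#' @param config a [pipeline_config()].
#' @return data.table with `region`, `context`, `group`, `n`, `median_level`,
#'   `letters`; pairwise p-values attached as the `pairwise` attribute.
#' @export
group_region_comparison <- function(region_meth, groups, config = pipeline_config()) {
  x <- merge(region_meth[!is.na(level)], groups[, .(gene_id, group)],
             by = "gene_id")
  excluded <- character()
  out <- list()
  pw <- list()
  for (rg in unique(x$region)) for (ctx in unique(x$context)) {
    y <- x[region == rg & context == ctx]
    sizes <- y[, .N, by = group]
    ok_groups <- sizes[N >= 2L][[1]]
    drop <- setdiff(as.character(unique(y$group)), as.character(ok_groups))
    if (length(drop))
      excluded <- union(excluded, paste(rg, ctx, drop, sep = "/"))
    y <- y[group %in% ok_groups]
    glev <- levels(droplevels(y$group))
    if (length(glev) < 2L) next
    pmat <- matrix(NA_real_, length(glev), length(glev),
                   dimnames = list(glev, glev))
    for (a in seq_along(glev)) for (b in seq_along(glev)) if (a < b) {
      pv <- mann_whitney_p(y[group == glev[a], level], y[group == glev[b], level])
      pmat[a, b] <- pmat[b, a] <- pv
      pw[[length(pw) + 1L]] <- data.table(region = rg, context = ctx,
                                          group_a = glev[a], group_b = glev[b],
                                          p = pv)
    }
    let <- compact_letter_display(pmat, config$group_test_alpha)
    med <- y[, .(n = .N, median_level = median(level)), by = group]
    med[, `:=`(region = rg, context = ctx)]
    med[, letters_ := let[match(as.character(group), glev)]]
    out[[length(out) + 1L]] <- med
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(region = character(), context = character(),
                      group = character(), n = integer(),
                      median_level = numeric(), letters_ = character())
  setnames(res, "letters_", "letters")
  setcolorder(res, c("region", "context", "group", "n", "median_level", "letters"))
  setorder(res, region, context, group)
  data.table::setattr(res, "pairwise", rbindlist(pw))
  data.table::setattr(res, "excluded_groups", excluded)
  res[]
}

#' Two-group flank profiles per sample
#'
#' For each sample, genes are split on that sample's TPM into the groups
#' 0 < TPM <= 1 and TPM > 1 (TPM = 0 genes are left out) and a full
#' gene metaprofile is computed per group.
#'
#' @param levels_by_sample named list of [site_levels()] tables.
#' @param annotation a [genome_annotation()].
#' @param expr TPM table.
#' @param config a [pipeline_config()].
#' @return data.table with `sample_id`, `group`, `context`, `zone`, `bin`,
#'   `level`, `n_sites`, `reads`.
#' @export
two_group_flank_profiles <- function(levels_by_sample, annotation, expr,
                                     config = pipeline_config()) {
  lo_b <- config$expression_breaks[2]
  rbindlist(lapply(names(levels_by_sample), function(sid) {
    tpm <- expr[[sid]]
    lo_ids <- expr$gene_id[tpm > 0 & tpm <= lo_b]
    hi_ids <- expr$gene_id[tpm > lo_b]
    rbindlist(lapply(list(c(sprintf("0<TPM<=%g", lo_b), list(lo_ids)),
                          c(sprintf("TPM>%g", lo_b), list(hi_ids))),
                     function(gr) {
      prof <- gene_te_profile(levels_by_sample[[sid]], annotation, "gene",
                              config, feature_ids = gr[[2]], group = gr[[1]])
      prof[, sample_id := sid]
      prof
    }))
  }))
}

#' Marker-segment methylation versus expression across ages
#'
#' For each marker segment (an interval, possibly starting upstream of its
#' gene, with a context of interest): the pooled weighted methylation level
#' per age (replicates pooled), the Pearson correlation of that level with
#' the per-age mean TPM of the gene, and with the age rank. Segments
#' uncovered in any age yield NA with a warning.
#'
#' @param samples named list of cytosine site tables.
#' @param segments data.table with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `context`.
#' @param expr TPM table.
#' @param sample_sheet sample sheet.
#' @return data.table with `gene_id`, one `level_<age>y` and `tpm_<age>y`
#'   column per age, `r_tpm`, `r_age`.
#' @export
marker_correlation <- function(samples, segments, expr, sample_sheet) {
  ages <- sort(unique(sample_sheet$age_years))
  seg <- copy(as.data.table(segments))[, seg_id := .I]
  stk <- rbindlist(lapply(names(samples), function(sid) {
    x <- samples[[sid]]
    dt <- data.table(chrom = x$chrom, pos0 = x$pos - 1L, context = x$context,
                     count_m = x$count_m, count_u = x$count_u)
    hit <- overlap_first(dt, seg)
    dt <- dt[!is.na(hit)][, seg_id := hit[!is.na(hit)]]
    dt <- dt[context == seg$context[seg_id]]
    dt[, sample_id := sid]
    dt
  }))
  stk <- merge(stk, sample_sheet[, .(sample_id, age_years)], by = "sample_id")
  agg <- stk[, .(m = sum(as.numeric(count_m)),
                 tot = sum(as.numeric(count_m + count_u))),
             by = .(seg_id, age_years)]
  out <- vector("list", nrow(seg))
  scols <- setdiff(names(expr), "gene_id")
  for (i in seq_len(nrow(seg))) {
    lv <- vapply(ages, function(a) {
      z <- agg[seg_id == i & age_years == a]
      if (nrow(z) == 0L || z$tot == 0) NA_real_ else z$m / z$tot
    }, numeric(1))
    tpm <- vapply(ages, function(a) {
      sids <- intersect(sample_sheet[age_years == a, sample_id], scols)
      gene_row <- expr[gene_id == seg$gene_id[i]]
      if (nrow(gene_row) == 0L || length(sids) == 0L) NA_real_ else
        mean(unlist(gene_row[, ..sids]))
    }, numeric(1))
    if (anyNA(lv))
      warning(sprintf("marker segment %s uncovered in at least one age",
                      seg$gene_id[i]))
    r_tpm <- if (anyNA(lv) || anyNA(tpm) || sd(lv) == 0 || sd(tpm) == 0)
      NA_real_ else cor(lv, tpm)
    r_age <- if (anyNA(lv) || sd(lv) == 0) NA_real_ else cor(lv, rank(ages))
    row <- data.table(gene_id = seg$gene_id[i])
    for (a in seq_along(ages)) row[, (paste0("level_", ages[a], "y")) := lv[a]]
    for (a in seq_along(ages)) row[, (paste0("tpm_", ages[a], "y")) := tpm[a]]
    row[, `:=`(r_tpm = r_tpm, r_age = r_age)]
    out[[i]] <- row
  }
  rbindlist(out)
}
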