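#' Methylation counts on the fixed 1000-bp DMR grid
#'
#' Sums methylated and unmethylated read counts of every cytosine (no
#' per-site coverage filter at this stage) per grid bin, sample and context.
#' The grid tiles each chromosome from 0 in `bin_size_dmr` steps; the last
#' bin may be short. A bin enters testing for a context only when it
#' contains at least one cytosine of that context and its total read count
#' reaches `coverage_min` in at least one sample; the `eligible` column
#' records this.
#'
#' @param samples named list of cytosine site tables.
#' @param config a [pipeline_config()].
#' @return data.table of class `bin_counts` with `chrom`, `bin_start`,
#'   `context`, `sample_id`, `n_m`, `n_u`, `eligible`.
#' @export
bin_counts <- function(samples, config = pipeline_config()) {
  bs <- config$bin_size_dmr
  long <- rbindlist(lapply(names(samples), function(sid) {
    x <- samples[[sid]]
    data.table(chrom = x$chrom, bin_start = ((x$pos - 1L) %/% bs) * bs,
               context = x$context, count_m = x$count_m, count_u = x$count_u,
               sample_id = sid)
  }))
  bcm <- long[, .(n_m = sum(as.numeric(count_m)), n_u = sum(as.numeric(count_u))),
              by = .(chrom, bin_start, context, sample_id)]
  bcm[, eligible := any(n_m + n_u >= config$coverage_min),
      by = .(chrom, bin_start, context)]
  setkey(bcm, chrom, bin_start, context)
  setattr(bcm, "class", c("bin_counts", class(bcm)))
  bcm[]
}

## Two-sided Fisher exact p for a 2x2 table, computed by summing all
## hypergeometric outcomes no more probable than the observed one (the
## classic convention, with the customary 1e-7 relative tolerance on ties).
fisher_p_one <- function(m1, u1, m2, u2) {
  k <- m1 + m2                      # methylated margin
  if (k == 0 || u1 + u2 == 0) return(1)
  lo <- max(0, k - (m2 + u2))
  hi <- min(k, m1 + u1)
  d <- dhyper(lo:hi, m1 + u1, m2 + u2, k)
  sum(d[d <= d[m1 - lo + 1] * (1 + 1e-7)])
}

#' Differential methylation test for one bin
#'
#' Replicate counts are pooled within each group; the two-sided Fisher
#' exact test is applied to the 2x2 table of methylated/unmethylated read
#' counts, and the effect is the difference of pooled weighted levels
#' (group 1 minus group 2). Vectorized over bins.
#'
#' @param m1,u1 pooled methylated/unmethylated counts of group 1.
#' @param m2,u2 pooled counts of group 2.
#' @return data.table with `diff` and `p`; both NA when a group has zero
#'   total count.
#' @export
test_bin <- function(m1, u1, m2, u2) {
  n <- length(m1)
  stopifnot(length(u1) == n, length(m2) == n, length(u2) == n)
  t1 <- m1 + u1
  t2 <- m2 + u2
  ok <- t1 > 0 & t2 > 0
  dif <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  dif[ok] <- m1[ok] / t1[ok] - m2[ok] / t2[ok]
  idx <- which(ok)
  p[idx] <- vapply(idx, function(i) fisher_p_one(m1[i], u1[i], m2[i], u2[i]),
                   numeric(1))
  data.table(diff = dif, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up with monotonicity enforcement; callers adjust
#' separately per context and comparison.
#'
#' @param p vector of p-values.
#' @return adjusted p-values (empty for empty input).
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Call DMRs between two sample groups on the bin grid
#'
#' Pools replicate counts within each group per eligible bin and context,
#' applies the two-sided Fisher exact test, adjusts p-values with BH within
#' each context, and calls a bin a DMR when the adjusted p is strictly below
#' `dmr_p_adj_max` and the absolute level difference reaches the
#' context-specific threshold (0.2/0.15/0.1 for CG/CHG/CHH at the
#' defaults). Direction is `hyper` when group 1 (conventionally the older
#' age) is more methylated.
#'
#' @param bcm a [bin_counts()] table.
#' @param group1,group2 character vectors of sample ids (group 1 is the
#'   older group of an age comparison).
#' @param comparison label stored with every record.
#' @param config a [pipeline_config()].
#' @return data.table with one row per tested bin and context: pooled
#'   levels, `diff` (group1 - group2), `p`, `p_adj`, `called`, `direction`.
#' @export
call_dmrs <- function(bcm, group1, group2, comparison = "g1_vs_g2",
                      config = pipeline_config()) {
  known <- unique(bcm$sample_id)
  bad <- setdiff(c(group1, group2), known)
  if (length(bad))
    stop("unknown sample id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pool <- function(ids, tag) {
    x <- bcm[sample_id %in% ids & eligible == TRUE,
             .(m = sum(n_m), u = sum(n_u)), by = .(chrom, bin_start, context)]
    setnames(x, c("m", "u"), paste0(c("m", "u"), tag))
  }
  tab <- merge(pool(group1, "1"), pool(group2, "2"),
               by = c("chrom", "bin_start", "context"), all = TRUE)
  for (cc in c("m1", "u1", "m2", "u2"))
    tab[is.na(get(cc)), (cc) := 0]
  res <- test_bin(tab$m1, tab$u1, tab$m2, tab$u2)
  tab[, level_older := fifelse(m1 + u1 > 0, m1 / (m1 + u1), NA_real_)]
  tab[, level_younger := fifelse(m2 + u2 > 0, m2 / (m2 + u2), NA_real_)]
  tab[, diff := res$diff]
  tab[, p := res$p]
  tab[, p_adj := adjust_fdr(p), by = context]
  thr <- config$dmr_diff_min
  tab[, called := !is.na(p_adj) & p_adj < config$dmr_p_adj_max &
        abs(diff) >= thr[context]]
  tab[, direction := fifelse(!called, NA_character_,
                             fifelse(diff > 0, "hyper", "hypo"))]
  tab[, comparison := comparison]
  setcolorder(tab, c("chrom", "bin_start", "context", "comparison"))
  setorder(tab, context, chrom, bin_start)
  tab[]
}
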