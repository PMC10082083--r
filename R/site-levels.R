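#' Per-site methylation levels with coverage filtering
#'
#' The methylation ratio of a cytosine is its methylated read count divided
#' by total reads (Cs / (Cs + Ts)); sites below the minimum coverage
#' (default 4 reads) are dropped. Optionally, symmetric CG sites on opposite
#' strands are merged into dyads by summing their counts (off by default).
#'
#' @param table cytosine site table (see [read_cytosine_report()]).
#' @param config a [pipeline_config()].
#' @return data.table with `chrom`, `pos`, `strand`, `context`,
#'   `subcontext`, `count_m`, `count_u`, `coverage`, `level`.
#' @export
site_levels <- function(table, config = pipeline_config()) {
  lv <- as.data.table(table)
  if (config$merge_cg_strands && nrow(lv)) {
    cg <- lv[context == "CG"]
    ## a minus-strand CG site at pos p pairs with the plus-strand site p-1
    cg[, pos := fifelse(strand == "-", pos - 1L, pos)]
    cg <- cg[, .(strand = "+", count_m = sum(count_m), count_u = sum(count_u),
                 context = "CG", subcontext = subcontext[1]), by = .(chrom, pos)]
    lv <- rbind(lv[context != "CG"], cg, use.names = TRUE, fill = TRUE)
  }
  lv[, coverage := count_m + count_u]
  lv <- lv[coverage >= config$coverage_min]
  lv[, level := count_m / coverage]
  setorder(lv, chrom, pos, strand)
  lv[]
}

#' Histogram of site-level methylation per context
#'
#' @param levels a [site_levels()] table.
#' @param breaks histogram breaks on `[0, 1]`.
#' @return data.table with `context`, `bin_low`, `bin_high`, `n`; masses per
#'   context sum to the number of covered sites.
#' @export
site_level_histogram <- function(levels, breaks = seq(0, 1, by = 0.05)) {
  levels[, {
    cl <- cut(level, breaks = breaks, include.lowest = TRUE, right = TRUE)
    tab <- table(cl)
    .(bin_low = head(breaks, -1), bin_high = tail(breaks, -1),
      n = as.integer(tab))
  }, by = context]
}

#' Bisulfite conversion rate from a lambda spike-in
#'
#' Counts are pooled over all lambda cytosines (summed, not site-averaged);
#' the conversion rate is one minus the pooled lambda methylation level.
#'
#' @param lambda_table cytosine site table of the unmethylated spike-in.
#' @return object of class `conversion_stats` with fields
#'   `lambda_methylated`, `lambda_total`, `conversion_rate`.
#' @export
conversion_rate <- function(lambda_table) {
  m <- sum(as.numeric(lambda_table$count_m))
  tot <- m + sum(as.numeric(lambda_table$count_u))
  if (tot == 0) stop("lambda spike-in has zero coverage", call. = FALSE)
  structure(list(lambda_methylated = m, lambda_total = tot,
                 conversion_rate = 1 - m / tot),
            class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("bisulfite conversion rate: %.4f (%d/%d lambda reads methylated)\n",
              x$conversion_rate, x$lambda_methylated, x$lambda_total))
  invisible(x)
}

#' Global methylation statistics
#'
#' Two companion statistics over covered sites of one context, optionally
#' restricted to a region set: (a) the count-weighted methylation level, sum
#' of methylated reads over sum of total reads; (b) the fraction of sites
#' called methylated, where a site is called methylated when a one-sided
#' binomial test of its methylated count against the non-conversion rate
#' survives BH FDR control (requires `conv`).
#'
#' @param levels a [site_levels()] table.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`, or `NULL` for all.
#' @param regions optional data.table of 0-based half-open intervals
#'   (`chrom`, `start`, `end`).
#' @param conv optional [conversion_rate()] result enabling the mC fraction.
#' @param config a [pipeline_config()].
#' @return list with `weighted_level`, `mc_fraction` (NA without `conv`)
#'   and `n_sites`.
#' @export
global_weighted_level <- function(levels, context = NULL, regions = NULL,
                                  conv = NULL, config = pipeline_config()) {
  lv <- levels
  if (!is.null(context)) lv <- lv[lv$context == context]
  if (!is.null(regions)) {
    lv <- copy(lv)[, pos0 := pos - 1L]
    hit <- overlap_first(lv, regions)
    lv <- lv[!is.na(hit)]
  }
  if (nrow(lv) == 0L)
    return(list(weighted_level = NA_real_, mc_fraction = NA_real_, n_sites = 0L))
  wl <- weighted_level(lv$count_m, lv$count_u)
  mc <- NA_real_
  if (!is.null(conv)) {
    bg <- 1 - conv$conversion_rate
    pv <- pbinom(lv$count_m - 1L, lv$coverage, bg, lower.tail = FALSE)
    called <- p.adjust(pv, "BH") < config$mc_call_fdr & lv$count_m > 0L
    mc <- mean(called)
  }
  list(weighted_level = wl, mc_fraction = mc, n_sites = nrow(lv))
}
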