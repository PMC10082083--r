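#' Simulate bisulfite read counts from true methylation states
#'
#' Coverage per cytosine is drawn from a negative binomial (mean
#' `mean_coverage`, size `coverage_dispersion`) to mimic the coverage
#' heterogeneity of real WGBS libraries. Methylated counts are binomial with
#' success probability `p_true + (1 - p_true) * conversion_failure_rate`, so
#' bisulfite non-conversion inflates observed methylation additively on the
#' unmethylated fraction only; no other error mode is modelled. A fully
#' unmethylated lambda spike-in table is generated per sample for
#' conversion-rate QC.
#'
#' @param states a [simulate_methylation_states()] result.
#' @param config a [sim_config()].
#' @return list with `samples` (named list of cytosine-report tables with
#'   columns chrom, pos, strand, count_m, count_u, context, subcontext) and
#'   `lambda` (named list of spike-in tables in the same layout).
#' @export
simulate_bs_counts <- function(states, config) {
  stopifnot(inherits(states, "meth_states"), inherits(config, "sim_config"))
  sites <- states$sites
  n <- nrow(sites)
  fail <- config$conversion_failure_rate
  withr::with_seed(derive_seed(config$seed, 3L), {
    samples <- lapply(states$sample_sheet$sample_id, function(sid) {
      cov <- rnbinom(n, size = config$coverage_dispersion, mu = config$mean_coverage)
      pt <- states$p[, sid]
      m <- rbinom(n, cov, pt + (1 - pt) * fail)
      data.table(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                 count_m = m, count_u = cov - m,
                 context = sites$context, subcontext = sites$subcontext)
    })
    names(samples) <- states$sample_sheet$sample_id

    nl <- config$lambda_n_sites
    lam_sub <- sample(c("CGA", "CAG", "CTT", "CAA", "CTA"), nl, replace = TRUE,
                      prob = c(0.2, 0.15, 0.25, 0.2, 0.2))
    lambda <- lapply(states$sample_sheet$sample_id, function(sid) {
      cov <- rnbinom(nl, size = config$coverage_dispersion, mu = config$mean_coverage)
      m <- rbinom(nl, cov, fail)
      data.table(chrom = "lambda", pos = seq_len(nl), strand = "+",
                 count_m = m, count_u = cov - m,
                 context = context_from_subcontext(lam_sub), subcontext = lam_sub)
    })
    names(lambda) <- states$sample_sheet$sample_id
    list(samples = samples, lambda = lambda)
  })
}
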