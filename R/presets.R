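#' Canned simulation study designs
#'
#' Convenience constructors for the synthetic studies that the package's
#' validation suite runs end to end. Each simply fills [sim_config()] with
#' a fixed design; all remain fully overridable.
#'
#' * `study_config()` - the default age-series design: 2 x 1 Mb genome,
#'   60 conifer-style genes (long-intron mixture), 45% TE content, 20x
#'   coverage, 8 samples (4 ages x 2 replicates), planted linear age-trend
#'   bins (including 200 CHG hyper bins rising 0.4 to 0.7), 100
#'   replicate-variable bins and 10 age-marker genes.
#' * `expression_study_config()` - a gene-dense design (260 compact genes
#'   on 2 x 1.2 Mb) without planted bins or markers, sized so the five TPM
#'   groups are all populated for methylation-expression comparisons.
#' * `uniform_levels_config()` - a single-chromosome design with noise-free
#'   class levels (no jitter, no gene factor, no non-conversion) for
#'   metaprofile fidelity checks; `base_levels` defaults to a flat level
#'   per context across all feature classes.
#' * `null_study_config()` - no planted signal of any kind, for DMR
#'   type-I-error calibration.
#'
#' @param seed master seed.
#' @param ... overrides passed through to [sim_config()].
#' @return a [sim_config()].
#' @export
study_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

#' @rdname study_config
#' @export
expression_study_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, n_chromosomes = 2L, chrom_length_bp = 1.2e6,
    n_genes = 260L, exons_per_gene_range = c(2L, 4L),
    intron_length_meanlog = log(600), intron_length_sdlog = 0.5,
    intron_frac_5kb = 0, intron_frac_20kb = 0,
    intergenic_gap_range = c(4300, 5300), te_fraction = 0.3,
    n_planted_age_dmrs = list(CG = c(hyper = 0L, hypo = 0L),
                              CHG = c(hyper = 0L, hypo = 0L),
                              CHH = c(hyper = 0L, hypo = 0L)),
    n_replicate_variable_bins = 0L, n_marker_genes = 0L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' @rdname study_config
#' @param flat_levels per-context flat level used for every feature class.
#' @export
uniform_levels_config <- function(seed = 1L,
                                  flat_levels = c(CG = 0.5, CHG = 0.4, CHH = 0.3),
                                  ...) {
  base <- lapply(CONTEXTS, function(ctx)
    c(exon = unname(flat_levels[ctx]), intron = unname(flat_levels[ctx]),
      TE = unname(flat_levels[ctx]), intergenic = unname(flat_levels[ctx])))
  names(base) <- CONTEXTS
  args <- list(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 1e6, n_genes = 30L,
    mean_coverage = 30, conversion_failure_rate = 0,
    base_levels = base, level_jitter_sd = 0,
    gene_meth_factor_range = c(1, 1),
    n_planted_age_dmrs = list(CG = c(hyper = 0L, hypo = 0L),
                              CHG = c(hyper = 0L, hypo = 0L),
                              CHH = c(hyper = 0L, hypo = 0L)),
    n_replicate_variable_bins = 0L, n_marker_genes = 0L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' @rdname study_config
#' @export
null_study_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 1e6,
    n_planted_age_dmrs = list(CG = c(hyper = 0L, hypo = 0L),
                              CHG = c(hyper = 0L, hypo = 0L),
                              CHH = c(hyper = 0L, hypo = 0L)),
    n_replicate_variable_bins = 0L, n_marker_genes = 0L, n_genes = 30L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
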