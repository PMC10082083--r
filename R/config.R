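#' Analysis pipeline configuration
#'
#' Collects every tunable threshold of the analysis stages with the study
#' defaults: minimum read coverage of 4 for a cytosine to be scored, 1000-bp
#' DMR bins, 5-kb replicate-correlation bins, 2-kb flanks with 20 fixed bins
#' and 20 proportional body bins for metaprofiles, 10/5 intron/exon panel
#' bins, context-specific DMR effect thresholds (0.2/0.15/0.1 for
#' CG/CHG/CHH) at adjusted p < 0.01, TPM group breaks \{0, 1, 10, 50\}, and a
#' two-comparison consensus rule for age DMRs.
#'
#' @param coverage_min minimum reads for a cytosine to enter level
#'   calculations.
#' @param bin_size_dmr width (bp) of the fixed DMR grid.
#' @param bin_size_corr width (bp) of replicate-correlation bins.
#' @param flank_bp flank width (bp) for metaprofiles and promoter/downstream
#'   region assignment.
#' @param n_body_bins,n_flank_bins number of proportional body bins and fixed
#'   flank bins of gene/TE metaprofiles.
#' @param intron_bins,exon_bins panel bins for intron-length profiles.
#' @param chrom_track_bin width (bp) of chromosome-track bins.
#' @param dmr_p_adj_max strict upper bound on BH-adjusted p for a DMR call.
#' @param dmr_diff_min named vector of minimum absolute methylation
#'   differences per context.
#' @param expression_breaks TPM breaks defining the five expression groups.
#' @param group_test_alpha significance threshold of pairwise Mann-Whitney
#'   tests in the letter display.
#' @param min_consensus_comparisons comparisons in which a DMR must recur
#'   (same direction) to enter the consensus set.
#' @param mc_call_fdr BH FDR for calling a cytosine methylated against the
#'   non-conversion background.
#' @param merge_cg_strands merge plus/minus CG sites into dyads before level
#'   calculations (off by default so strand consistency stays checkable).
#' @param stem_max_step maximum per-step unit change of model profiles.
#' @param stem_permutations permutation passes for model-profile significance.
#' @param intron_length_breaks interior breaks (bp) of the four intron-length
#'   groups.
#' @param intron_count_breaks interior breaks of the intron-count groups used
#'   by the exon-only profile.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(coverage_min = 4L,
                            bin_size_dmr = 1000L,
                            bin_size_corr = 5000L,
                            flank_bp = 2000L,
                            n_body_bins = 20L,
                            n_flank_bins = 20L,
                            intron_bins = 10L,
                            exon_bins = 5L,
                            chrom_track_bin = 2e7,
                            dmr_p_adj_max = 0.01,
                            dmr_diff_min = c(CG = 0.2, CHG = 0.15, CHH = 0.1),
                            expression_breaks = c(0, 1, 10, 50),
                            group_test_alpha = 0.01,
                            min_consensus_comparisons = 2L,
                            mc_call_fdr = 0.05,
                            merge_cg_strands = FALSE,
                            stem_max_step = 1L,
                            stem_permutations = 1000L,
                            intron_length_breaks = c(1000, 5000, 20000),
                            intron_count_breaks = c(0, 2, 5)) {
  cfg <- list(coverage_min = as.integer(coverage_min),
              bin_size_dmr = as.integer(bin_size_dmr),
              bin_size_corr = as.integer(bin_size_corr),
              flank_bp = as.integer(flank_bp),
              n_body_bins = as.integer(n_body_bins),
              n_flank_bins = as.integer(n_flank_bins),
              intron_bins = as.integer(intron_bins),
              exon_bins = as.integer(exon_bins),
              chrom_track_bin = as.numeric(chrom_track_bin),
              dmr_p_adj_max = dmr_p_adj_max,
              dmr_diff_min = dmr_diff_min,
              expression_breaks = expression_breaks,
              group_test_alpha = group_test_alpha,
              min_consensus_comparisons = as.integer(min_consensus_comparisons),
              mc_call_fdr = mc_call_fdr,
              merge_cg_strands = isTRUE(merge_cg_strands),
              stem_max_step = as.integer(stem_max_step),
              stem_permutations = as.integer(stem_permutations),
              intron_length_breaks = intron_length_breaks,
              intron_count_breaks = intron_count_breaks)
  pos <- c("coverage_min", "bin_size_dmr", "bin_size_corr", "flank_bp",
           "n_body_bins", "n_flank_bins", "intron_bins", "exon_bins",
           "chrom_track_bin", "min_consensus_comparisons")
  for (nm in pos)
    if (cfg[[nm]] <= 0) stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  if (!all(CONTEXTS %in% names(cfg$dmr_diff_min)))
    stop("'dmr_diff_min' needs named entries for CG, CHG and CHH", call. = FALSE)
  if (any(cfg$dmr_diff_min <= 0 | cfg$dmr_diff_min > 1))
    stop("'dmr_diff_min' entries must lie in (0, 1]", call. = FALSE)
  stopifnot_scalar_prob(cfg$dmr_p_adj_max, "dmr_p_adj_max")
  stopifnot_scalar_prob(cfg$group_test_alpha, "group_test_alpha")
  structure(cfg, class = "pipeline_config")
}

#' Synthetic methylome configuration
#'
#' Defines the simulated study: genome geometry, gene and TE architecture,
#' background methylation per feature class and context, bisulfite coverage
#' and non-conversion, the planted age-trend and replicate-variable bins, and
#' the age-marker genes. Defaults emulate an age series of 2, 5, 14 and 35
#' years with two replicates per age at roughly 20x coverage on a compact
#' two-chromosome genome.
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it, so an identical configuration reproduces identical output.
#' @param n_chromosomes,chrom_length_bp genome geometry.
#' @param n_genes number of gene models to place (an error is raised when
#'   the chromosomes cannot host them).
#' @param exons_per_gene_range inclusive range of exon counts per gene.
#' @param exon_length_meanlog,exon_length_sdlog log-normal exon lengths (bp).
#' @param intron_length_meanlog,intron_length_sdlog log-normal short-intron
#'   lengths (bp).
#' @param intron_frac_5kb,intron_frac_20kb fraction of introns drawn in
#'   (5, 20] kb and > 20 kb respectively.
#' @param intergenic_gap_range uniform range (bp) of gaps between genes.
#' @param te_fraction target fraction of the genome covered by TEs; TEs are
#'   inserted preferentially into long introns, never into exons.
#' @param base_composition A/C/G/T probabilities of the random genome.
#' @param mean_coverage,coverage_dispersion negative-binomial read coverage
#'   per cytosine (mean and size parameter).
#' @param conversion_failure_rate probability that an unmethylated cytosine
#'   escapes bisulfite conversion and is read as methylated.
#' @param base_levels per-context named list of methylation probabilities for
#'   the feature classes exon, intron, TE and intergenic.
#' @param level_jitter_sd SD of Gaussian site-level jitter added to the class
#'   level (shared by all samples; clipped to `[0, 1]`).
#' @param gene_meth_factor_range uniform range of the per-gene multiplier
#'   applied to exon and flank methylation; it creates the between-gene
#'   variation that expression is coupled to.
#' @param ages,replicates_per_age the age series (years, strictly increasing)
#'   and replication.
#' @param n_planted_age_dmrs named list per context with `hyper`/`hypo`
#'   counts of planted 1000-bp age-trend bins.
#' @param planted_base_level,planted_effect starting level and total change
#'   of planted bins; levels run linearly over the age index (hyper) or in
#'   reverse (hypo).
#' @param n_replicate_variable_bins number of planted age-independent bins in
#'   which the two replicates of every age differ.
#' @param replicate_bin_level,replicate_bin_offset replicate-1 level and the
#'   replicate-2 offset of those bins (offset at least the CG DMR threshold).
#' @param n_marker_genes number of age-marker genes; each carries a segment
#'   from `marker_upstream_bp` upstream of the TSS into its (forced long)
#'   first intron whose CHG methylation declines with age while TPM rises.
#' @param marker_upstream_bp,marker_intron_span_bp marker segment geometry.
#' @param marker_chg_levels strictly decreasing per-age CHG levels of marker
#'   segments.
#' @param marker_tpm strictly increasing per-age TPM of marker genes.
#' @param marker_tpm_noise_sd log-normal noise SD on marker TPM.
#' @param expr_intercept,expr_slope,expr_noise_sd linear coupling of log TPM
#'   to gene exon+downstream methylation plus log-normal gene noise.
#' @param expr_sample_noise_sd per-sample log-normal TPM noise.
#' @param zero_expr_fraction fraction of genes silenced (TPM = 0), taken from
#'   the most methylated end of the latent expression scale.
#' @param lambda_n_sites cytosines of the unmethylated lambda spike-in.
#' @param srna_bin_bp,srna_coupling sRNA density track bin width and the
#'   per-length-class log-linear coupling to methylation (0 = independent).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1e6,
                       n_genes = 60L,
                       exons_per_gene_range = c(1L, 8L),
                       exon_length_meanlog = log(250), exon_length_sdlog = 0.35,
                       intron_length_meanlog = log(700), intron_length_sdlog = 0.7,
                       intron_frac_5kb = 0.15,
                       intron_frac_20kb = 0.05,
                       intergenic_gap_range = c(3000, 9000),
                       te_fraction = 0.45,
                       base_composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       mean_coverage = 20,
                       coverage_dispersion = 8,
                       conversion_failure_rate = 0.005,
                       base_levels = list(
                         CG  = c(exon = 0.60, intron = 0.75, TE = 0.90, intergenic = 0.55),
                         CHG = c(exon = 0.45, intron = 0.65, TE = 0.80, intergenic = 0.50),
                         CHH = c(exon = 0.03, intron = 0.06, TE = 0.12, intergenic = 0.05)),
                       level_jitter_sd = 0.05,
                       gene_meth_factor_range = c(0.25, 1.3),
                       ages = c(2L, 5L, 14L, 35L),
                       replicates_per_age = 2L,
                       n_planted_age_dmrs = list(
                         CG  = c(hyper = 120L, hypo = 40L),
                         CHG = c(hyper = 200L, hypo = 60L),
                         CHH = c(hyper = 0L, hypo = 0L)),
                       planted_base_level = 0.4,
                       planted_effect = 0.3,
                       n_replicate_variable_bins = 100L,
                       replicate_bin_level = 0.35,
                       replicate_bin_offset = 0.25,
                       n_marker_genes = 10L,
                       marker_upstream_bp = 2500L,
                       marker_intron_span_bp = 8000L,
                       marker_chg_levels = c(0.70, 0.55, 0.40, 0.25),
                       marker_tpm = c(10, 40, 70, 100),
                       marker_tpm_noise_sd = 0.05,
                       expr_intercept = 5,
                       expr_slope = -8,
                       expr_noise_sd = 0.8,
                       expr_sample_noise_sd = 0.1,
                       zero_expr_fraction = 0.25,
                       lambda_n_sites = 60000L,
                       srna_bin_bp = 5000L,
                       srna_coupling = c("21" = 0, "22" = 0, "24" = 0)) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_chromosomes <- as.integer(n_chromosomes)
  cfg$chrom_length_bp <- as.numeric(chrom_length_bp)
  cfg$n_genes <- as.integer(n_genes)
  cfg$ages <- as.integer(ages)
  cfg$replicates_per_age <- as.integer(replicates_per_age)
  ## -- validation ------------------------------------------------------
  if (any(diff(cfg$ages) <= 0)) stop("'ages' must be strictly increasing", call. = FALSE)
  stopifnot_scalar_prob(cfg$conversion_failure_rate, "conversion_failure_rate")
  stopifnot_scalar_prob(cfg$te_fraction, "te_fraction")
  stopifnot_scalar_prob(cfg$zero_expr_fraction, "zero_expr_fraction")
  for (ctx in CONTEXTS) {
    lv <- cfg$base_levels[[ctx]]
    if (is.null(lv) || !all(c("exon", "intron", "TE", "intergenic") %in% names(lv)))
      stop(sprintf("base_levels$%s must name exon, intron, TE and intergenic", ctx),
           call. = FALSE)
    if (any(lv < 0 | lv > 1))
      stop(sprintf("base_levels$%s outside [0, 1]", ctx), call. = FALSE)
  }
  if (cfg$planted_base_level < 0 || cfg$planted_base_level + cfg$planted_effect > 1)
    stop("planted_effect pushes planted levels outside [0, 1]", call. = FALSE)
  if (cfg$replicate_bin_level + cfg$replicate_bin_offset > 1)
    stop("replicate-variable bin levels outside [0, 1]", call. = FALSE)
  n_ages <- length(cfg$ages)
  if (length(cfg$marker_chg_levels) != n_ages || length(cfg$marker_tpm) != n_ages)
    stop("marker level/TPM series must have one value per age", call. = FALSE)
  if (cfg$n_marker_genes > 0 &&
      (any(diff(cfg$marker_chg_levels) >= 0) || any(diff(cfg$marker_tpm) <= 0)))
    stop("marker CHG levels must strictly decrease and marker TPM strictly increase",
         call. = FALSE)
  if (any(cfg$marker_chg_levels < 0 | cfg$marker_chg_levels > 1))
    stop("marker_chg_levels outside [0, 1]", call. = FALSE)
  if (cfg$mean_coverage <= 0 || cfg$coverage_dispersion <= 0)
    stop("coverage parameters must be positive", call. = FALSE)
  if (abs(sum(cfg$base_composition) - 1) > 1e-8)
    stop("base_composition must sum to 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Read a configuration from YAML
#'
#' Values present in the file override defaults of [sim_config()] or
#' [pipeline_config()]; everything else keeps its default, and the merged
#' configuration is re-validated.
#'
#' @param path YAML file.
#' @param type `"sim"` or `"pipeline"`.
#' @return a validated configuration object.
#' @export
read_config_yaml <- function(path, type = c("sim", "pipeline")) {
  type <- match.arg(type)
  vals <- restore_named_vectors(yaml::read_yaml(path))
  ctor <- if (type == "sim") sim_config else pipeline_config
  known <- names(formals(ctor))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(ctor, vals)
}

#' Write a configuration to YAML
#'
#' @param config a `sim_config` or `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(listify_named_vectors(unclass(config)), path)
  invisible(path)
}

## YAML drops names of atomic vectors; map named vectors to YAML maps and
## back so configurations round-trip
listify_named_vectors <- function(x) {
  if (is.list(x)) lapply(x, listify_named_vectors)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

restore_named_vectors <- function(x, top = TRUE) {
  if (!is.list(x)) return(x)
  if (!top) {
    scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1))
    if (length(x) && !is.null(names(x)) && all(scalar) && all(nzchar(names(x))))
      return(unlist(x))
  }
  lapply(x, restore_named_vectors, top = FALSE)
}
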