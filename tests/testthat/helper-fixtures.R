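## Shared fixtures, built lazily once per test session. Heavy simulated
## datasets are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

## the default age-series study (planted DMRs, replicate bins, markers)
study_sim <- function() fixture("study_sim", function()
  simulate_methylome(study_config(seed = 42L)))

study_pipeline <- function() fixture("study_pipeline", function() {
  sim <- study_sim()
  run_age_pipeline(sim$counts$samples, sim$sample_sheet,
                   pipeline_config(), stem_seed = 101L)
})

## gene-dense design for methylation-expression analyses
expr_sim <- function() fixture("expr_sim", function()
  simulate_methylome(expression_study_config(seed = 42L)))

expr_levels <- function() fixture("expr_levels", function()
  site_levels(data.table::rbindlist(expr_sim()$counts$samples),
              pipeline_config()))

## a small fast design for operation-level tests
tiny_config <- function(seed = 3L, ...) {
  args <- list(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 2e5, n_genes = 8L,
    exons_per_gene_range = c(2L, 4L), intron_frac_5kb = 0.1,
    intron_frac_20kb = 0,
    n_planted_age_dmrs = list(CG = c(hyper = 5L, hypo = 2L),
                              CHG = c(hyper = 5L, hypo = 2L),
                              CHH = c(hyper = 0L, hypo = 0L)),
    n_replicate_variable_bins = 5L, n_marker_genes = 2L,
    lambda_n_sites = 3000L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_sim <- function() fixture("tiny_sim", function()
  simulate_methylome(tiny_config()))

## a dense uniform-level site table over one synthetic gene for exact
## metaprofile arithmetic: a site every `by` bp, constant counts
uniform_sites <- function(chrom = "chrA", chrom_len = 10000L, by = 5L,
                          m = 5L, u = 5L, context = "CG", strand = "+") {
  pos <- seq(3L, chrom_len - 2L, by = by)
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         count_m = m, count_u = u, context = context,
                         subcontext = ifelse(context == "CG", "CGA",
                                             ifelse(context == "CHG", "CAG", "CAA")))
}

one_gene_annotation <- function(chrom = "chrA", chrom_len = 10000L,
                                start = 3000L, end = 6000L, strand = "+",
                                exon_bounds = NULL) {
  if (is.null(exon_bounds)) exon_bounds <- list(c(start, end))
  exons <- data.table::rbindlist(lapply(seq_along(exon_bounds), function(i)
    data.table::data.table(gene_id = "g1", chrom = chrom, strand = strand,
                           start = exon_bounds[[i]][1], end = exon_bounds[[i]][2],
                           exon_rank = NA_integer_)))
  data.table::setorder(exons, start)
  exons[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N))]
  genome_annotation(
    stats::setNames(chrom_len, chrom),
    data.table::data.table(gene_id = "g1", chrom = chrom, strand = strand,
                           start = start, end = end, is_marker = FALSE),
    exons,
    data.table::data.table(te_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           te_class = character()))
}

## independent two-sided Fisher oracle: explicit hypergeometric table
## probabilities from lchoose, summed over all tables no more probable than
## the observed one (for all observed values of one margin triple at once)
fisher_oracle_triple <- function(r1, r2, k) {
  lo <- max(0L, k - r2)
  hi <- min(k, r1)
  x <- lo:hi
  pr <- exp(lchoose(r1, x) + lchoose(r2, k - x) - lchoose(r1 + r2, k))
  thr <- outer(pr, pr * (1 + 1e-7), "<=")    # [x, observed]
  colSums(thr * pr)
}

## brute-force BH: min over the tail of p * n / rank
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)
    adj[i] <- min(1, min(p[o[r:n]] * n / (r:n)))
  }
  adj
}

## exact two-sided rank-sum p by full enumeration (no ties)
rank_sum_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  idx <- utils::combn(n, n1)
  r <- rank(pool)
  stats_all <- apply(idx, 2, function(j) sum(r[j]))
  w_obs <- sum(r[seq_len(n1)])
  lower <- mean(stats_all <= w_obs)
  upper <- mean(stats_all >= w_obs)
  min(1, 2 * min(lower, upper))
}
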