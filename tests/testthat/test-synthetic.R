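test_that("genome generation is deterministic and respects the empty case", {
  cfg <- tiny_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$annotation$tes, g2$annotation$tes)

  g0 <- generate_genome(tiny_config(n_genes = 0L, n_marker_genes = 0L))
  expect_equal(nrow(g0$annotation$genes), 0L)
  expect_gt(nrow(g0$annotation$tes), 0L)
})

test_that("TE insertion hits the target genome fraction", {
  cfg <- sim_config(seed = 9L, te_fraction = 0.6, n_chromosomes = 1L,
                    chrom_length_bp = 2e6, n_genes = 60L)
  gen <- generate_genome(cfg)
  frac <- sum(gen$annotation$tes$end - gen$annotation$tes$start) / 2e6
  expect_lt(abs(frac - 0.6), 0.05)
  ## TEs never sit inside exons
  ex <- gen$annotation$tes[gen$annotation$exons,
                           on = .(chrom, start < end, end > start), nomatch = NULL]
  expect_equal(nrow(ex), 0L)
})

test_that("a too-small genome for the requested genes raises a sizing error", {
  expect_error(generate_genome(tiny_config(chrom_length_bp = 2e4, n_genes = 50L)),
               "too short")
})

test_that("intron length mixture responds to the configured fractions", {
  gen <- generate_genome(sim_config(seed = 4L, n_genes = 80L,
                                    n_marker_genes = 0L,
                                    intron_frac_5kb = 0.3, intron_frac_20kb = 0))
  ir <- introns(gen$annotation)
  frac_long <- mean(ir$end - ir$start > 5000)
  expect_gt(frac_long, 0.2)
  expect_lt(frac_long, 0.4)
})

test_that("planted age bins carry exact linear level series", {
  sim <- tiny_sim()
  st <- sim$states
  gt <- st$ground_truth$planted_dmr_bins
  hyper_cg <- gt[context == "CG" & direction == "hyper"][1]
  expect_equal(unlist(hyper_cg[, .(level_2y, level_5y, level_14y, level_35y)],
                      use.names = FALSE),
               c(0.4, 0.5, 0.6, 0.7))
  ## the p matrix reproduces the series for CG sites of that bin
  s <- st$sites
  idx <- which(s$chrom == hyper_cg$chrom & s$context == "CG" &
                 (s$pos - 1L) %/% 1000L * 1000L == hyper_cg$bin_start)
  expect_gt(length(idx), 0)
  sheet <- st$sample_sheet
  for (a in seq_along(c(2, 5, 14, 35))) {
    cols <- sheet[age_years == c(2, 5, 14, 35)[a], sample_id]
    expect_equal(unique(as.vector(st$p[idx, cols])),
                 c(0.4, 0.5, 0.6, 0.7)[a])
  }
  ## hypo bins run in reverse
  hypo <- gt[direction == "hypo"][1]
  expect_equal(hypo$level_2y, 0.7)
  expect_equal(hypo$level_35y, 0.4)
})

test_that("planted categories are disjoint and resolve to the grid", {
  gt <- tiny_sim()$states$ground_truth
  planted <- gt$planted_dmr_bins[, .(chrom, bin_start)]
  repvar <- gt$replicate_variable_bins
  expect_equal(nrow(unique(planted)[repvar, on = c("chrom", "bin_start"),
                                    nomatch = NULL]), 0L)
  expect_true(all(planted$bin_start %% 1000 == 0))
  expect_true(all(repvar$bin_start %% 1000 == 0))
})

test_that("marker ground truth is perfectly anti-correlated before noise", {
  gt <- tiny_sim()$states$ground_truth$marker_segments
  expect_equal(nrow(gt), 2L)
  lev <- unlist(gt[1, .(level_2y, level_5y, level_14y, level_35y)])
  tpm <- unlist(gt[1, .(tpm_2y, tpm_5y, tpm_14y, tpm_35y)])
  expect_true(all(diff(lev) < 0))
  expect_true(all(diff(tpm) > 0))
  ## markers lie within their gene plus the stated upstream offset
  ann <- tiny_sim()$annotation
  seg <- merge(gt, ann$genes, by = c("gene_id", "chrom"))
  up <- tiny_config()$marker_upstream_bp
  expect_true(all((seg$strand == "+" & seg$start.x >= seg$start.y - up &
                     seg$end.x <= seg$end.y) |
                  (seg$strand == "-" & seg$end.x <= seg$end.y + up &
                     seg$start.x >= seg$start.y)))
})

test_that("no planted bins requested yields empty ground truth", {
  sim <- simulate_methylome(null_study_config(seed = 5L,
                                              chrom_length_bp = 1.5e5,
                                              n_genes = 4L, lambda_n_sites = 500L))
  expect_equal(nrow(sim$states$ground_truth$planted_dmr_bins), 0L)
  expect_equal(nrow(sim$states$ground_truth$replicate_variable_bins), 0L)
})

test_that("bisulfite counts conserve coverage and honour degenerate settings", {
  sim <- tiny_sim()
  cnt <- sim$counts$samples[[1]]
  expect_true(all(cnt$count_m >= 0 & cnt$count_u >= 0))
  expect_lt(abs(mean(cnt$count_m + cnt$count_u) - 20), 1)

  ## p_true = 1 with no conversion failure gives fully methylated reads
  st <- sim$states
  st$p[] <- 1
  cfg0 <- tiny_config(conversion_failure_rate = 0)
  cnt1 <- simulate_bs_counts(st, cfg0)$samples[[1]]
  expect_true(all(cnt1$count_u == 0L))
})

test_that("counts are byte-identical when re-simulated from one config", {
  cfg <- tiny_config(seed = 17L)
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(a$counts$samples, b$counts$samples)
  expect_identical(a$expression, b$expression)
})

test_that("site-level background matches the configured class levels", {
  cfg <- uniform_levels_config(seed = 6L, n_genes = 10L,
                               chrom_length_bp = 3e5, lambda_n_sites = 500L)
  sim <- simulate_methylome(cfg)
  cnt <- data.table::rbindlist(sim$counts$samples)
  cg <- cnt[context == "CG"]
  lvl <- sum(cg$count_m) / sum(cg$count_m + cg$count_u)
  se <- sqrt(0.5 * 0.5 / sum(cg$count_m + cg$count_u))
  expect_lt(abs(lvl - 0.5), 3 * se + 1e-6)
})

test_that("expression coupling produces the configured degenerate cases", {
  cfg <- tiny_config(expr_slope = 0, expr_noise_sd = 0,
                     expr_sample_noise_sd = 0, zero_expr_fraction = 0,
                     n_marker_genes = 0L)
  sim <- simulate_methylome(cfg)
  tpm <- unlist(sim$expression[, -1])
  expect_equal(length(unique(round(tpm, 6))), 1L)

  ## markers rise strictly with age per replicate
  sim2 <- tiny_sim()
  mk <- sim2$annotation$genes[is_marker == TRUE, gene_id]
  e <- sim2$expression[gene_id == mk[1]]
  ages <- c(2, 5, 14, 35)
  per_age <- vapply(ages, function(a)
    mean(unlist(e[, sim2$sample_sheet[age_years == a, sample_id], with = FALSE])),
    numeric(1))
  expect_true(all(diff(per_age) > 0))
})

test_that("negative methylation-expression coupling is recovered genome-wide", {
  sim <- study_sim()
  gm <- sim$states$gene_meth
  tpm <- rowMeans(as.matrix(sim$expression[, -1]))
  keep <- !sim$annotation$genes$is_marker
  ct <- suppressWarnings(
    cor.test(gm$true_meth[keep], tpm[keep], method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
})
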