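test_that("cytosine contexts and sub-contexts are classified on both strands", {
  ctx <- classify_contexts(c(chrA = "TTCGA"))
  plus <- ctx[strand == "+"]
  expect_equal(plus$pos, 3L)
  expect_equal(plus$context, "CG")
  expect_equal(plus$subcontext, "CGA")
  minus <- ctx[strand == "-"]
  expect_equal(minus$pos, 4L)            # the G pairing the plus-strand C
  expect_equal(minus$context, "CG")
  expect_equal(minus$subcontext, "CGA")

  ctx2 <- classify_contexts(c(chrA = "ACAGT"))
  expect_equal(ctx2[strand == "+" & pos == 2L, .(context, subcontext)],
               data.table::data.table(context = "CHG", subcontext = "CAG"))

  ## ambiguous bases are excluded and tallied
  ctx3 <- classify_contexts(c(chrA = "ACNGTACGT"))
  expect_gt(attr(ctx3, "n_ambiguous"), 0)
  expect_false(any(grepl("N", ctx3$subcontext)))
})

test_that("sub-context inventories are 4 CG + 3 CHG + 9 CHH", {
  gen <- tiny_sim()$genome
  ctx <- classify_contexts(gen)
  inv <- ctx[, .(n = data.table::uniqueN(subcontext)), by = context]
  expect_equal(inv[context == "CG", n], 4L)
  expect_equal(inv[context == "CHG", n], 3L)
  expect_equal(inv[context == "CHH", n], 9L)
})

test_that("site levels apply the coverage filter and the ratio formula", {
  tbl <- data.table::data.table(
    chrom = "c", pos = c(10L, 20L, 30L), strand = "+",
    count_m = c(7L, 2L, 0L), count_u = c(3L, 1L, 4L),
    context = "CG", subcontext = "CGA")
  lv <- site_levels(tbl, pipeline_config())
  expect_equal(nrow(lv), 2L)             # the 2/1 site has coverage 3 < 4
  expect_equal(lv[pos == 10L, level], 0.7)
  expect_equal(lv[pos == 30L, level], 0)

  hist <- site_level_histogram(lv)
  expect_equal(sum(hist$n), nrow(lv))
})

test_that("merging CG strands into dyads sums counts", {
  tbl <- data.table::data.table(
    chrom = "c", pos = c(10L, 11L), strand = c("+", "-"),
    count_m = c(3L, 5L), count_u = c(2L, 0L),
    context = "CG", subcontext = "CGA")
  lv <- site_levels(tbl, pipeline_config(merge_cg_strands = TRUE))
  expect_equal(nrow(lv), 1L)
  expect_equal(lv$level, 8 / 10)
})

test_that("conversion rate pools lambda counts", {
  lam <- data.table::data.table(chrom = "lambda", pos = 1:100, strand = "+",
                                count_m = c(5L, rep(0L, 99)),
                                count_u = c(5L, rep(10L, 99)),
                                context = "CHH", subcontext = "CTT")
  cv <- conversion_rate(lam)
  expect_equal(cv$conversion_rate, 1 - 5 / 1000)
  lam0 <- data.table::copy(lam)[, `:=`(count_m = 0L, count_u = 0L)]
  expect_error(conversion_rate(lam0), "zero")
  lam1 <- data.table::copy(lam)[, count_m := 0L]
  expect_equal(conversion_rate(lam1)$conversion_rate, 1)
})

test_that("global weighted level and mC fraction behave as defined", {
  tbl <- data.table::data.table(
    chrom = "c", pos = c(1L, 2L), strand = "+",
    count_m = c(5L, 10L), count_u = c(5L, 0L),
    context = "CG", subcontext = "CGA")
  lv <- site_levels(tbl, pipeline_config())
  g <- global_weighted_level(lv, "CG")
  expect_equal(g$weighted_level, 0.75)

  ## weighted level is invariant to splitting a site's reads in two
  split1 <- data.table::data.table(
    chrom = "c", pos = c(1L, 1L, 2L), strand = c("+", "-", "+"),
    count_m = c(2L, 3L, 10L), count_u = c(3L, 2L, 0L),
    context = "CG", subcontext = "CGA")
  g2 <- global_weighted_level(site_levels(split1, pipeline_config()), "CG")
  expect_equal(g2$weighted_level, g$weighted_level)

  ## all-unmethylated sites give a zero mC fraction
  conv <- structure(list(conversion_rate = 0.995), class = "conversion_stats")
  zero <- data.table::data.table(chrom = "c", pos = 1:50, strand = "+",
                                 count_m = 0L, count_u = 20L,
                                 context = "CG", subcontext = "CGA")
  gz <- global_weighted_level(site_levels(zero, pipeline_config()), "CG",
                              conv = conv)
  expect_equal(gz$mc_fraction, 0)

  ## strongly methylated simulated sites are nearly all called
  set.seed(1)
  hot <- data.table::data.table(chrom = "c", pos = 1:2000, strand = "+",
                                count_m = rbinom(2000, 20, 0.6),
                                count_u = 0L, context = "CG",
                                subcontext = "CGA")
  hot[, count_u := 20L - count_m]
  gh <- global_weighted_level(site_levels(hot, pipeline_config()), "CG",
                              conv = conv)
  expect_gte(gh$mc_fraction, 0.95)

  expect_true(is.na(global_weighted_level(lv[0], "CG")$weighted_level))
})

test_that("replicate correlation reaches the exact degenerate values", {
  lv <- site_levels(tiny_sim()$counts$samples[[1]], pipeline_config())
  same <- replicate_correlation(lv, lv)
  expect_true(all(abs(same$pearson_r - 1) < 1e-12))

  anti <- data.table::copy(lv)
  data.table::setnames(anti, c("count_m", "count_u"), c("count_u", "count_m"))
  anti[, level := count_m / coverage]
  flipped <- replicate_correlation(lv, anti)
  expect_true(all(abs(flipped$pearson_r + 1) < 1e-12))

  tiny <- lv[pos < 5000]                  # a single 5-kb bin
  expect_true(is.na(replicate_correlation(tiny, tiny)[context == "CG", pearson_r]))
})

test_that("chromosome tracks carry the full sub-context inventory", {
  sim <- tiny_sim()
  lv <- site_levels(sim$counts$samples[[1]], pipeline_config())
  ct <- chromosome_tracks(lv, sim$annotation, sim$srna, bin_size = 50000)
  nsub <- ct$methylation[subcontext != "all",
                         .(n = data.table::uniqueN(subcontext)), by = context]
  expect_equal(sum(nsub$n), 16L)
  ## a bin without gene midpoints has zero gene density
  expect_true(all(ct$features$gene_density >= 0))
  expect_equal(ct$features[, sum(gene_density)], nrow(sim$annotation$genes))
  ## short terminal bins are flagged
  expect_true(all(ct$features$short == (ct$features$width < 50000)))
})

test_that("sRNA-methylation correlation finds construction and independence", {
  sim <- tiny_sim()
  lv <- site_levels(sim$counts$samples[[1]], pipeline_config())
  bl <- lv[, .(m = sum(count_m), cov = sum(coverage)),
           by = .(chrom, bin_start = ((pos - 1L) %/% 5000L) * 5000L)]
  prop <- bl[, .(chrom, start = bin_start, end = bin_start + 5000L,
                 score = m / cov)]
  r1 <- track_methylation_correlation(prop, lv, 5000)
  expect_gt(r1[context == "combined", pearson_r], 0.99)

  const <- data.table::copy(prop)[, score := 1]
  r2 <- track_methylation_correlation(const, lv, 5000)
  expect_true(all(is.na(r2$pearson_r)))

  r3 <- track_methylation_correlation(sim$srna[["21nt"]], lv, 5000)
  expect_lt(abs(r3[context == "combined", pearson_r]), 0.5)
})

test_that("plus- and minus-strand profiles agree on symmetric states", {
  sim <- fixture("fidelity_flat", function()
    simulate_methylome(uniform_levels_config(seed = 31L)))
  lv <- site_levels(data.table::rbindlist(sim$counts$samples[1:2]),
                    pipeline_config())
  pp <- gene_te_profile(lv[strand == "+"], sim$annotation, "gene")
  pm <- gene_te_profile(lv[strand == "-"], sim$annotation, "gene")
  cmp <- merge(pp[, .(context, bin, lp = level)],
               pm[, .(context, bin, lm = level)], by = c("context", "bin"))
  expect_lt(max(abs(cmp$lp - cmp$lm), na.rm = TRUE), 0.05)
})
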