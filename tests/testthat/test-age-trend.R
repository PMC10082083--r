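mk_dmr_table <- function(bins, context, direction, comparison = "x") {
  data.table::data.table(chrom = "c", bin_start = bins, context = context,
                         comparison = comparison, called = TRUE,
                         direction = direction)
}

test_that("replicate-noise exclusion is context-matched", {
  age <- list(a35v2 = mk_dmr_table(c(0L, 1000L, 2000L), "CG", "hyper"))
  reps <- list(rep14 = mk_dmr_table(1000L, "CG", "hyper"),
               rep02 = mk_dmr_table(2000L, "CHG", "hyper"))
  res <- replicate_dmr_exclusion(age, reps)
  kept <- res$reserved$a35v2
  ## the CG replicate bin is excluded; the CHG-only one is retained
  expect_equal(sort(kept$bin_start), c(0L, 2000L))
  expect_equal(res$stats[context == "CG", n_excluded], 1L)
  expect_equal(res$stats[context == "CG", reserved_fraction], 2 / 3)
  expect_error(replicate_dmr_exclusion(age, list()), "required")
})

test_that("consensus requires direction-matched recurrence", {
  r <- list(
    c1 = mk_dmr_table(c(0L, 1000L, 3000L), "CG", "hyper", "c1"),
    c2 = mk_dmr_table(c(0L, 3000L), "CG", c("hyper", "hypo"), "c2"),
    c3 = mk_dmr_table(2000L, "CG", "hyper", "c3"))
  cons <- consensus_dmrs(r)
  ## bin 0: hyper twice -> consensus; 1000/2000: once -> no; 3000: conflict
  expect_equal(cons$bin_start, 0L)
  expect_equal(cons$direction, "hyper")
  expect_equal(attr(cons, "n_conflicted"), 1L)
  ## raising the recurrence requirement never grows the set
  cons3 <- consensus_dmrs(r, pipeline_config(min_consensus_comparisons = 3L))
  expect_lte(nrow(cons3), nrow(cons))
  expect_error(consensus_dmrs(r[1]), "at least two")
})

test_that("trajectories pool replicates within ages", {
  sheet <- data.table::data.table(
    sample_id = c("a1", "a2", "b1", "b2"),
    age_years = c(2L, 2L, 35L, 35L), replicate = c(1L, 2L, 1L, 2L))
  bcm <- data.table::CJ(sample_id = sheet$sample_id, bin_start = 0L)
  bcm[, `:=`(chrom = "c", context = "CG", eligible = TRUE)]
  bcm[, n_m := c(2, 4, 8, 10)]
  bcm[, n_u := c(8, 6, 2, 0)]
  tr <- trajectories(bcm, data.table::data.table(chrom = "c", bin_start = 0L,
                                                 context = "CG"), sheet)
  expect_equal(tr$level_2y, 6 / 20)
  expect_equal(tr$level_35y, 18 / 20)

  ## a bin uncovered in one age is dropped
  bcm2 <- bcm[sample_id %in% c("a1", "a2")]
  tr2 <- trajectories(bcm2, data.table::data.table(chrom = "c", bin_start = 0L,
                                                   context = "CG"), sheet)
  expect_equal(nrow(tr2), 0L)
})

test_that("planted bins trace their linear trajectories", {
  pipe <- study_pipeline()
  sim <- study_sim()
  pl <- sim$states$ground_truth$planted_dmr_bins[context == "CHG" &
                                                   direction == "hyper"]
  tr <- pipe$trajectories[pl[, .(chrom, bin_start, context)],
                          on = c("chrom", "bin_start", "context"),
                          nomatch = NULL]
  expect_gt(nrow(tr), 150)
  lev <- as.matrix(tr[, .(level_2y, level_5y, level_14y, level_35y)])
  expect_lt(max(abs(sweep(lev, 2, c(0.4, 0.5, 0.6, 0.7)))), 0.12)
  ## the mean consensus-hyper trajectory is non-decreasing
  expect_true(all(diff(colMeans(lev)) > 0))
})

test_that("model profiles enumerate unit-step vectors and assign by correlation", {
  prof <- stem_profiles(1L, 4L)
  expect_equal(nrow(prof), 27L)
  expect_true(all(prof[, 1] == 0))
  expect_true(all(abs(prof[, -1] - prof[, -4]) <= 1))

  X <- rbind(c(0.1, 0.3, 0.5, 0.7),
             c(0.7, 0.5, 0.3, 0.1),
             c(0.2, 0.2, 0.2, 0.2))
  colnames(X) <- paste0("level_", c(2, 5, 14, 35), "y")
  res <- stem_cluster(X, c = 1L, n_permutations = 50L, seed = 2L)
  asg <- attr(res, "assignments")
  expect_equal(res[profile_id == asg$profile_id[1], profile], "0,1,2,3")
  expect_equal(res[profile_id == asg$profile_id[2], profile], "0,-1,-2,-3")
  flat <- res[profile == "0,0,0,0"]
  expect_equal(asg$profile_id[3], flat$profile_id)
  expect_true(is.na(flat$p))
})

test_that("no model profile is significant on pure-noise trajectories", {
  clean <- 0L
  for (run in 1:8) {
    set.seed(1000L + run)
    X <- matrix(runif(200 * 4), ncol = 4)
    colnames(X) <- paste0("level_", c(2, 5, 14, 35), "y")
    res <- stem_cluster(X, c = 1L, n_permutations = 200L, seed = run)
    if (!any(res$p_adj < 0.05, na.rm = TRUE)) clean <- clean + 1L
  }
  expect_gte(clean, 7L)
})

test_that("element assignment is an exhaustive priority partition", {
  ann <- genome_annotation(
    c(c = 50000L),
    data.table::data.table(gene_id = "g1", chrom = "c", strand = "+",
                           start = 10000L, end = 20000L, is_marker = FALSE),
    data.table::data.table(gene_id = "g1", chrom = "c", strand = "+",
                           start = c(10000L, 19000L), end = c(11000L, 20000L),
                           exon_rank = 1:2),
    data.table::data.table(te_id = "t1", chrom = "c", start = 14000L,
                           end = 15000L, te_class = "LTR/Gypsy"))
  dmrs <- data.table::data.table(
    chrom = "c", bin_start = c(14000L, 9000L, 12000L, 21000L, 30000L),
    context = "CG")
  res <- assign_elements(dmrs, ann)
  a <- res$assignment
  expect_equal(a[bin_start == 14000L, element], "TE")      # TE inside intron
  expect_equal(a[bin_start == 9000L, element], "promoter")  # 1 kb upstream
  expect_equal(a[bin_start == 12000L, element], "gene_body")
  expect_equal(a[bin_start == 21000L, element], "downstream")
  expect_equal(a[bin_start == 30000L, element], "intergenic")
  expect_equal(res$counts[, sum(n)], nrow(dmrs))
})

test_that("genes link to DMRs within 2 kb but not beyond", {
  ann <- genome_annotation(
    c(c = 50000L),
    data.table::data.table(gene_id = c("g1", "g2"), chrom = "c", strand = "+",
                           start = c(10000L, 11000L), end = c(20000L, 21000L),
                           is_marker = FALSE),
    data.table::data.table(gene_id = c("g1", "g2"), chrom = "c", strand = "+",
                           start = c(10000L, 11000L), end = c(20000L, 21000L),
                           exon_rank = 1L),
    data.table::data.table(te_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           te_class = character()))
  dmrs <- data.table::data.table(chrom = "c", bin_start = c(8000L, 7000L),
                                 context = "CG", direction = "hyper")
  res <- genes_with_dmrs(dmrs, ann)
  ## 8000-8999 is within 2 kb of g1 (TSS 10000) but 7000-7999 is not;
  ## the overlapping g2 (TSS 11000) only reaches back to 9000, so g1 alone links
  expect_equal(res[hyper == TRUE, gene_id], "g1")
  dmr2 <- data.table::data.table(chrom = "c", bin_start = 12000L,
                                 context = "CG", direction = "hypo")
  res2 <- genes_with_dmrs(dmr2, ann)
  expect_equal(sort(res2[hypo == TRUE, gene_id]), c("g1", "g2"))
})
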