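test_that("a uniformly methylated gene yields a flat 60-bin profile", {
  ann <- one_gene_annotation()
  lv <- site_levels(uniform_sites(), pipeline_config())
  prof <- gene_te_profile(lv, ann, "gene")
  cg <- prof[context == "CG"]
  expect_equal(nrow(cg), 60L)
  expect_true(all(cg$level == 0.5))
  expect_equal(sort(unique(cg$zone)), c("body", "downstream", "upstream"))
})

test_that("minus-strand genes mirror plus-strand genes with mirrored states", {
  len <- 10000L
  ## an asymmetric level ramp along the chromosome
  ramp <- uniform_sites(chrom_len = len)
  ramp[, count_m := as.integer(round(9 * pos / len))]
  ramp[, count_u := 10L - count_m]
  mirror <- data.table::copy(ramp)
  mirror[, pos := len + 1L - pos]
  data.table::setorder(mirror, pos)
  lv_p <- site_levels(ramp, pipeline_config())
  lv_m <- site_levels(mirror, pipeline_config())
  ann_p <- one_gene_annotation(start = 3000L, end = 6000L, strand = "+")
  ann_m <- one_gene_annotation(start = len - 6000L, end = len - 3000L,
                               strand = "-")
  pp <- gene_te_profile(lv_p, ann_p, "gene")
  pm <- gene_te_profile(lv_m, ann_m, "gene")
  expect_equal(pm[context == "CG", level], pp[context == "CG", level],
               tolerance = 1e-12)
})

test_that("profiles pool across features by read counts", {
  ann2 <- genome_annotation(
    c(chrA = 20000L),
    data.table::data.table(gene_id = c("g1", "g2"), chrom = "chrA",
                           strand = "+", start = c(3000L, 12000L),
                           end = c(6000L, 15000L), is_marker = FALSE),
    data.table::data.table(gene_id = c("g1", "g2"), chrom = "chrA",
                           strand = "+", start = c(3000L, 12000L),
                           end = c(6000L, 15000L), exon_rank = 1L),
    data.table::data.table(te_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           te_class = character()))
  sites <- uniform_sites(chrom_len = 20000L)
  sites[pos > 10000L, `:=`(count_m = 9L, count_u = 1L)]   # g2 at 0.9, g1 at 0.5
  lv <- site_levels(sites, pipeline_config())
  both <- gene_te_profile(lv, ann2, "gene")
  g1 <- gene_te_profile(lv, ann2, "gene", feature_ids = "g1")
  g2 <- gene_te_profile(lv, ann2, "gene", feature_ids = "g2")
  cmp <- merge(merge(g1[, .(context, bin, l1 = level, r1 = reads)],
                     g2[, .(context, bin, l2 = level, r2 = reads)],
                     by = c("context", "bin")),
               both[, .(context, bin, lb = level)], by = c("context", "bin"))
  cmp <- cmp[!is.na(l1) & !is.na(l2)]
  expect_equal(cmp$lb, with(cmp, (l1 * r1 + l2 * r2) / (r1 + r2)),
               tolerance = 1e-12)
})

test_that("exon-only profiles report the 3' skew per intron-count group", {
  ## uniform exon methylation: skew is zero
  ann <- one_gene_annotation(exon_bounds = list(c(3000, 3500), c(4500, 5000),
                                                c(5500, 6000)))
  lv <- site_levels(uniform_sites(), pipeline_config())
  eo <- exon_only_profile(lv, ann)
  expect_equal(eo$skew[group == "1-2" & context == "CG", skew], 0)
  ## groups without genes keep NA rows
  expect_true(all(is.na(eo$profile[group == ">=6", level])))
  expect_true(is.na(eo$skew[group == ">=6" & context == "CG", skew]))

  ## a 3'-rising exon gradient gives a positive skew
  ramp <- uniform_sites()
  ramp[, count_m := as.integer(round(9 * pos / 10000))]
  ramp[, count_u := 10L - count_m]
  eo2 <- exon_only_profile(site_levels(ramp, pipeline_config()), ann)
  expect_gt(eo2$skew[group == "1-2" & context == "CG", skew], 0.1)

  ## on the minus strand the same genomic gradient reverses the skew sign
  ann_m <- one_gene_annotation(strand = "-",
                               exon_bounds = list(c(3000, 3500), c(4500, 5000),
                                                  c(5500, 6000)))
  eo3 <- exon_only_profile(site_levels(ramp, pipeline_config()), ann_m)
  expect_lt(eo3$skew[group == "1-2" & context == "CG", skew], -0.1)
})

test_that("intron panels step between exon and intron levels", {
  ann <- one_gene_annotation(chrom_len = 30000L, start = 3000L, end = 21000L,
                             exon_bounds = list(c(3000, 4000), c(10000, 11000),
                                                c(20000, 21000)))
  sites <- uniform_sites(chrom_len = 30000L)
  ## exons at 0.3, everything else 0.8
  in_exon <- (sites$pos > 3000 & sites$pos <= 4000) |
    (sites$pos > 10000 & sites$pos <= 11000) |
    (sites$pos > 20000 & sites$pos <= 21000)
  sites[, count_m := ifelse(in_exon, 3L, 8L)]
  sites[, count_u := 10L - count_m]
  lv <- site_levels(sites, pipeline_config())
  ip <- intron_length_profiles(lv, ann)
  p1 <- ip[context == "CG" & intron_rank == 1 & len_group == "5-20kb"]
  expect_equal(nrow(p1), 20L)
  expect_true(all(p1[zone == "intron", level] == 0.8))
  expect_true(all(p1[zone != "intron", level] == 0.3))
  ## the second intron (9 kb) lands in the same group with identical panels
  p2 <- ip[context == "CG" & intron_rank == 2 & len_group == "5-20kb"]
  expect_equal(p2[zone == "intron", level], p1[zone == "intron", level])
  ## groups without qualifying introns stay NA
  expect_true(all(is.na(ip[len_group == ">20kb", level])))
})

test_that("region methylation matches its definitions and nesting", {
  ann <- one_gene_annotation(exon_bounds = list(c(3000, 4000), c(5000, 6000)))
  sites <- uniform_sites()
  lv <- site_levels(sites, pipeline_config())
  rm_ <- region_methylation(lv, ann)
  cg <- rm_[context == "CG" & gene_id == "g1"]
  expect_equal(cg[region == "exon", level], 0.5)
  ## nesting of upstream windows by read mass
  expect_lte(cg[region == "up500", reads], cg[region == "up1000", reads])
  expect_lte(cg[region == "up1000", reads], cg[region == "up2000", reads])

  ## explicit exon counts: sites 5/10 and 10/10 pool to 0.75
  two <- data.table::data.table(
    chrom = "chrA", pos = c(3500L, 3600L), strand = "+",
    count_m = c(5L, 10L), count_u = c(5L, 0L), context = "CG",
    subcontext = "CGA")
  rm2 <- region_methylation(site_levels(two, pipeline_config()), ann)
  expect_equal(rm2[context == "CG" & region == "exon", level], 0.75)

  ## an intronless gene has body level equal to exon level and NA introns
  ann1 <- one_gene_annotation()
  rm3 <- region_methylation(lv, ann1)
  expect_equal(rm3[context == "CG" & region == "body", level],
               rm3[context == "CG" & region == "exon", level])
  expect_true(is.na(rm3[context == "CG" & region == "intron", level]))
})

test_that("flank clipping at chromosome bounds never produces negative regions", {
  ann <- one_gene_annotation(chrom_len = 5000L, start = 500L, end = 4500L)
  lv <- site_levels(uniform_sites(chrom_len = 5000L), pipeline_config())
  prof <- gene_te_profile(lv, ann, "gene")
  expect_true(all(prof$reads >= 0))
  rm_ <- region_methylation(lv, ann)
  expect_true(all(rm_$reads >= 0))
})
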