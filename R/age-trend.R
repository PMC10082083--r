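#' Exclude replicate-noise DMRs from age-comparison DMRs
#'
#' DMRs called between the two biological replicates within each age mark
#' bins whose methylation varies independently of age (naturally occurring
#' epigenetic drift). Any age-comparison DMR bin that is also a
#' replicate-DMR bin of the same context in any age is excluded; the rest
#' are reserved for age-trend analysis. Per-context excluded and reserved
#' fractions are reported, as is the fraction of replicate DMRs that
#' overlap age DMRs.
#'
#' @param age_dmrs named list of [call_dmrs()] tables for the age
#'   comparisons.
#' @param replicate_dmrs named list of [call_dmrs()] tables for the
#'   within-age replicate comparisons.
#' @return list with `reserved` (named list of filtered called-DMR tables),
#'   `blacklist` (replicate-DMR bins per context) and `stats` (per-context
#'   exclusion summary).
#' @export
replicate_dmr_exclusion <- function(age_dmrs, replicate_dmrs) {
  if (length(replicate_dmrs) == 0L)
    stop("replicate DMR sets are required", call. = FALSE)
  blk <- unique(rbindlist(lapply(replicate_dmrs, function(x)
    x[called == TRUE, .(chrom, bin_start, context)])))
  all_age <- unique(rbindlist(lapply(age_dmrs, function(x)
    x[called == TRUE, .(chrom, bin_start, context)])))
  excluded <- all_age[blk, on = c("chrom", "bin_start", "context"), nomatch = NULL]
  stats <- rbindlist(lapply(CONTEXTS, function(ctx) {
    n_age <- nrow(all_age[context == ctx])
    n_exc <- nrow(excluded[context == ctx])
    n_blk <- nrow(blk[context == ctx])
    data.table(context = ctx, n_age_dmrs = n_age, n_replicate_dmrs = n_blk,
               n_excluded = n_exc,
               excluded_fraction = if (n_age > 0) n_exc / n_age else NA_real_,
               reserved_fraction = if (n_age > 0) 1 - n_exc / n_age else NA_real_,
               replicate_overlap_fraction =
                 if (n_blk > 0) n_exc / n_blk else NA_real_)
  }))
  reserved <- lapply(age_dmrs, function(x) {
    y <- x[called == TRUE]
    y[!blk, on = c("chrom", "bin_start", "context")]
  })
  list(reserved = reserved, blacklist = blk, stats = stats)
}

#' Consensus hyper- and hypo-DMRs across age comparisons
#'
#' A bin is a consensus DMR for a context when it is called in the same
#' direction in at least `min_consensus_comparisons` comparisons; bins
#' called hyper in one comparison and hypo in another are dropped (tallied
#' in the `n_conflicted` attribute).
#'
#' @param reserved_list named list of reserved DMR tables (from
#'   [replicate_dmr_exclusion()]), one per comparison.
#' @param config a [pipeline_config()].
#' @return data.table with `chrom`, `bin_start`, `context`, `direction`,
#'   `n_comparisons`.
#' @export
consensus_dmrs <- function(reserved_list, config = pipeline_config()) {
  if (length(reserved_list) < 2L)
    stop("at least two comparisons are required for a consensus", call. = FALSE)
  stk <- rbindlist(lapply(reserved_list, function(x)
    x[, .(chrom, bin_start, context, direction)]))
  agg <- stk[, .(n_hyper = sum(direction == "hyper"),
                 n_hypo = sum(direction == "hypo")),
             by = .(chrom, bin_start, context)]
  conflicted <- agg[n_hyper > 0 & n_hypo > 0]
  agg <- agg[!(n_hyper > 0 & n_hypo > 0)]
  mc <- config$min_consensus_comparisons
  out <- agg[n_hyper >= mc | n_hypo >= mc,
             .(chrom, bin_start, context,
               direction = fifelse(n_hyper >= mc, "hyper", "hypo"),
               n_comparisons = pmax(n_hyper, n_hypo))]
  setorder(out, context, chrom, bin_start)
  data.table::setattr(out, "n_conflicted", nrow(conflicted))
  out[]
}

#' Per-age methylation trajectories of bins
#'
#' For each requested bin and context, replicate counts are pooled within
#' each age and the weighted level taken, giving an ordered series over the
#' ages. Bins with zero coverage in any age are dropped.
#'
#' @param bcm a [bin_counts()] table.
#' @param bins data.table with `chrom`, `bin_start`, `context`.
#' @param sample_sheet sheet mapping samples to ages.
#' @return data.table with `chrom`, `bin_start`, `context` and one
#'   `level_<age>y` column per age.
#' @export
trajectories <- function(bcm, bins, sample_sheet) {
  ages <- sort(unique(sample_sheet$age_years))
  x <- bcm[unique(bins[, .(chrom, bin_start, context)]),
           on = c("chrom", "bin_start", "context"), nomatch = NULL]
  x <- merge(x, sample_sheet[, .(sample_id, age_years)], by = "sample_id")
  agg <- x[, .(m = sum(n_m), tot = sum(n_m + n_u)),
           by = .(chrom, bin_start, context, age_years)]
  agg[, level := fifelse(tot > 0, m / tot, NA_real_)]
  wide <- data.table::dcast(agg, chrom + bin_start + context ~ age_years,
                            value.var = "level")
  for (a in ages)
    if (!as.character(a) %in% names(wide)) wide[, (as.character(a)) := NA_real_]
  setnames(wide, as.character(ages), paste0("level_", ages, "y"))
  wide <- wide[complete.cases(wide)]
  setorder(wide, context, chrom, bin_start)
  wide[]
}

#' Enumerate model profiles for short time-series clustering
#'
#' All integer step vectors starting at 0 whose successive changes lie in
#' `-c..c`; with 4 time points and c = 1 this yields 27 profiles including
#' the flat reference profile.
#'
#' @param c maximum unit change per step.
#' @param n_points number of time points.
#' @return matrix (profiles x time points); row order is lexicographic in
#'   the step vectors, which fixes the tie-break order.
#' @export
stem_profiles <- function(c = 1L, n_points = 4L) {
  steps <- as.matrix(do.call(expand.grid, rep(list(seq(-c, c)), n_points - 1L)))
  ord <- do.call(order, as.data.frame(steps))
  steps <- steps[ord, , drop = FALSE]
  prof <- cbind(0L, t(apply(steps, 1L, cumsum)))
  dimnames(prof) <- list(apply(prof, 1L, paste, collapse = ","), NULL)
  prof
}

## all permutations of seq_len(m) as rows of a matrix
permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(k)
    cbind(k, sub + (sub >= k))))
}

## assign each trajectory (rows of X) to the best-correlated profile;
## returns profile row indices (ties -> lowest index); flat rows get NA
assign_profiles <- function(X, prof) {
  keep <- apply(prof, 1L, sd) > 0
  P <- prof[keep, , drop = FALSE]
  Pc <- P - rowMeans(P)
  Pn <- Pc / sqrt(rowSums(Pc^2))
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  flat <- nrm == 0
  out <- rep(NA_integer_, nrow(X))
  if (any(!flat)) {
    Xn <- Xc[!flat, , drop = FALSE] / nrm[!flat]
    cc <- Xn %*% t(Pn)
    best <- max.col(cc, ties.method = "first")
    out[!flat] <- which(keep)[best]
  }
  out
}

#' Model-profile clustering of methylation trajectories
#'
#' A short-time-series clustering in the STEM spirit: candidate profiles
#' are all unit-step model profiles ([stem_profiles()]); each trajectory is
#' standardized (first value subtracted, scaled by its range) and assigned
#' to the profile with the highest Pearson correlation (ties to the lower
#' profile index; flat trajectories go to the flat reference profile, which
#' is excluded from significance ranking). Profile significance compares
#' the observed assignment count against the expected rate estimated by
#' permuting the time order of every trajectory, with a one-sided binomial
#' tail p-value and BH adjustment across profiles.
#'
#' @param traj a [trajectories()] table (or matrix of series in columns
#'   ordered by age).
#' @param c maximum unit change per profile step.
#' @param n_permutations full permutation passes.
#' @param seed seed for the permutation stream.
#' @param config a [pipeline_config()] (supplies defaults for `c` and
#'   `n_permutations`).
#' @return data.table with one row per profile: `profile_id`, `profile`
#'   (comma-separated values), `n_assigned`, `expected`, `p`, `log_p`,
#'   `p_adj` and `rank` (1 = most significant; the flat profile and the
#'   rank are NA-separated). The per-trajectory assignment is attached as
#'   the `assignments` attribute.
#' @export
stem_cluster <- function(traj, c = NULL, n_permutations = NULL, seed = 1L,
                         config = pipeline_config()) {
  c <- c %||% config$stem_max_step
  n_permutations <- n_permutations %||% config$stem_permutations
  lev_cols <- grep("^level_", names(traj), value = TRUE)
  X <- if (is.matrix(traj)) traj else as.matrix(traj[, ..lev_cols])
  if (nrow(X) == 0L) stop("no trajectories to cluster", call. = FALSE)
  prof <- stem_profiles(c, ncol(X))
  flat_id <- which(apply(prof, 1L, sd) == 0)

  ## standardize: subtract first value, scale by range unless degenerate
  Xs <- X - X[, 1L]
  rng <- apply(Xs, 1L, function(r) diff(range(r)))
  Xs[rng > 0, ] <- Xs[rng > 0, , drop = FALSE] / rng[rng > 0]

  asg <- assign_profiles(Xs, prof)
  asg[is.na(asg)] <- flat_id
  n_eval <- sum(asg != flat_id)
  obs <- tabulate(asg, nbins = nrow(prof))

  perm_tot <- numeric(nrow(prof))
  all_perms <- permutations_of(ncol(Xs))
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      ## each trajectory gets an independent random time-order permutation
      pi_row <- sample.int(nrow(all_perms), nrow(Xs), replace = TRUE)
      Xp <- Xs
      for (j in seq_len(ncol(Xs)))
        Xp[, j] <- Xs[cbind(seq_len(nrow(Xs)), all_perms[pi_row, j])]
      ap <- assign_profiles(Xp, prof)
      ap[is.na(ap)] <- flat_id
      perm_tot <- perm_tot + tabulate(ap, nbins = nrow(prof))
    }
  })
  n_flat <- sum(asg == flat_id)
  n_test <- nrow(X) - n_flat
  expected_rate <- if (n_test > 0)
    perm_tot / (n_permutations * nrow(X)) else rep(0, nrow(prof))

  res <- data.table(profile_id = seq_len(nrow(prof)),
                    profile = rownames(prof),
                    n_assigned = obs,
                    expected = expected_rate * nrow(X))
  res[, p := pbinom(n_assigned - 1L, nrow(X), expected_rate, lower.tail = FALSE)]
  res[, log_p := pbinom(n_assigned - 1L, nrow(X), expected_rate,
                        lower.tail = FALSE, log.p = TRUE)]
  res[profile_id == flat_id, c("p", "log_p") := .(NA_real_, NA_real_)]
  res[, p_adj := NA_real_]
  res[profile_id != flat_id, p_adj := adjust_fdr(p)]
  res[, rank_ := frank(log_p, na.last = "keep", ties.method = "first")]
  setnames(res, "rank_", "rank")
  asg_dt <- data.table(row = seq_len(nrow(X)), profile_id = asg)
  if (!is.matrix(traj))
    asg_dt <- cbind(traj[, .(chrom, bin_start, context)], asg_dt)
  data.table::setattr(res, "assignments", asg_dt)
  res[]
}

#' Assign DMR bins to genomic elements
#'
#' Exhaustive, exclusive assignment with priority TE > gene body > proximal
#' promoter (2 kb upstream of the TSS, strand-aware) > downstream (2 kb
#' past the TES) > intergenic; one base pair of overlap suffices.
#'
#' @param dmrs data.table with `chrom`, `bin_start`, `context` (bins on the
#'   DMR grid).
#' @param annotation a [genome_annotation()].
#' @param config a [pipeline_config()] (`flank_bp` sets promoter and
#'   downstream widths, `bin_size_dmr` the bin width).
#' @return list with `counts` (context x element, zeros kept) and
#'   `assignment` (per-bin element).
#' @export
assign_elements <- function(dmrs, annotation, config = pipeline_config()) {
  elements <- c("TE", "gene_body", "promoter", "downstream", "intergenic")
  bins <- unique(dmrs[, .(chrom, bin_start, context)])
  bins[, element := "intergenic"]
  layers <- list(
    downstream = gene_flanks(annotation, config$flank_bp, "down"),
    promoter = gene_flanks(annotation, config$flank_bp, "up"),
    gene_body = annotation$genes[, .(chrom, start, end)],
    TE = annotation$tes[, .(chrom, start, end)])
  bs <- config$bin_size_dmr
  q <- data.table(chrom = bins$chrom, start = bins$bin_start,
                  end = bins$bin_start + bs - 1L)       # inclusive
  for (nm in names(layers)) {
    iv <- layers[[nm]]
    if (is.null(iv) || nrow(iv) == 0L) next
    b <- iv[, .(chrom, start, end = end - 1L)]
    setkey(b, chrom, start, end)
    hits <- foverlaps(q, b, type = "any", nomatch = NULL, which = TRUE)
    if (nrow(hits)) bins[unique(hits$xid), element := nm]
  }
  counts <- bins[, .N, by = .(context, element)]
  full <- CJ(context = unique(bins$context), element = elements)
  counts <- counts[full, on = c("context", "element")]
  counts[is.na(N), N := 0L]
  setnames(counts, "N", "n")
  list(counts = counts[], assignment = bins[])
}

#' Genes linked to DMRs
#'
#' A gene is linked to a DMR when the DMR bin overlaps the gene body or its
#' 2-kb up/downstream flanks; a gene may be both hyper- and hypo-linked,
#' and a DMR may link several overlapping genes.
#'
#' @param dmrs data.table with `chrom`, `bin_start`, `context`, `direction`.
#' @param annotation a [genome_annotation()].
#' @param config a [pipeline_config()].
#' @return data.table with `gene_id`, `context`, `hyper`, `hypo`.
#' @export
genes_with_dmrs <- function(dmrs, annotation, config = pipeline_config()) {
  g <- annotation$genes
  if (nrow(g) == 0L || nrow(dmrs) == 0L)
    return(data.table(gene_id = character(), context = character(),
                      hyper = logical(), hypo = logical()))
  ext <- g[, .(gene_id, chrom,
               start = pmax(start - config$flank_bp, 0L),
               end = end + config$flank_bp)]
  bs <- config$bin_size_dmr
  q <- data.table(chrom = dmrs$chrom, start = dmrs$bin_start,
                  end = dmrs$bin_start + bs - 1L,
                  context = dmrs$context, direction = dmrs$direction)
  b <- ext[, .(gene_id, chrom, start, end = end - 1L)]
  setkey(b, chrom, start, end)
  hits <- foverlaps(q, b, type = "any", nomatch = NULL, which = TRUE)
  if (nrow(hits) == 0L)
    return(data.table(gene_id = character(), context = character(),
                      hyper = logical(), hypo = logical()))
  j <- data.table(gene_id = ext$gene_id[hits$yid],
                  context = q$context[hits$xid],
                  direction = q$direction[hits$xid])
  out <- j[, .(hyper = any(direction == "hyper", na.rm = TRUE),
               hypo = any(direction == "hypo", na.rm = TRUE)),
           by = .(gene_id, context)]
  setorder(out, gene_id, context)
  out[]
}

#' Run the full age-DMR pipeline
#'
#' Convenience wrapper: builds bin counts, calls DMRs for the big-gap age
#' comparisons (oldest vs youngest and the two flanking gaps) and for the
#' within-age replicate comparisons, excludes replicate-noise bins, forms
#' the direction-matched consensus, extracts trajectories of all reserved
#' bins and clusters them per context.
#'
#' @param samples named list of cytosine site tables.
#' @param sample_sheet sample sheet.
#' @param config a [pipeline_config()].
#' @param stem_seed seed for profile-significance permutations.
#' @param comparisons list of `c(older, younger)` age pairs; defaults to
#'   the three big-gap comparisons of a four-age design.
#' @return list with `bcm`, `age_dmrs`, `replicate_dmrs`, `exclusion`,
#'   `reserved`, `consensus`, `trajectories` and `stem` (per context).
#' @export
run_age_pipeline <- function(samples, sample_sheet, config = pipeline_config(),
                             stem_seed = 1L, comparisons = NULL) {
  ages <- sort(unique(sample_sheet$age_years))
  if (is.null(comparisons)) {
    n <- length(ages)
    comparisons <- list(c(ages[n], ages[1]), c(ages[n], ages[2]),
                        c(ages[n - 1], ages[1]))
  }
  bcm <- bin_counts(samples, config)
  ids_of <- function(a) sample_sheet[age_years == a, sample_id]
  age_dmrs <- lapply(comparisons, function(cp)
    call_dmrs(bcm, ids_of(cp[1]), ids_of(cp[2]),
              sprintf("%dy_vs_%dy", cp[1], cp[2]), config))
  names(age_dmrs) <- vapply(comparisons, function(cp)
    sprintf("%dy_vs_%dy", cp[1], cp[2]), "")
  rep_dmrs <- lapply(ages, function(a) {
    ss <- sample_sheet[age_years == a]
    reps <- sort(unique(ss$replicate))
    call_dmrs(bcm, ss[replicate == reps[1], sample_id],
              ss[replicate == reps[2], sample_id],
              sprintf("rep_within_%dy", a), config)
  })
  names(rep_dmrs) <- sprintf("rep_within_%dy", ages)
  excl <- replicate_dmr_exclusion(age_dmrs, rep_dmrs)
  cons <- consensus_dmrs(excl$reserved, config)
  reserved_bins <- unique(rbindlist(lapply(excl$reserved, function(x)
    x[, .(chrom, bin_start, context)])))
  traj <- trajectories(bcm, reserved_bins, sample_sheet)
  stem <- lapply(CONTEXTS, function(ctx) {
    tr <- traj[context == ctx]
    if (nrow(tr) < 2L) return(NULL)
    stem_cluster(tr, seed = stem_seed, config = config)
  })
  names(stem) <- CONTEXTS
  list(bcm = bcm, age_dmrs = age_dmrs, replicate_dmrs = rep_dmrs,
       exclusion = excl, reserved = excl$reserved, consensus = cons,
       trajectories = traj, stem = stem)
}
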