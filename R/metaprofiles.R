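## Positional aggregation: gene/TE body+flank metaprofiles, exon-only
## profiles, intron-length panels and per-gene region methylation.
## Pooling across features is read-count-weighted throughout.

## Build bin intervals for a set of features: fixed-width flank bins (100 bp
## at the defaults) and proportional body bins, bin index running 5'->3' in
## transcript orientation (upstream flank 1..nf, body nf+1..nf+nb, downstream
## flank nf+nb+1..2nf+nb).
feature_profile_bins <- function(features, chrom_lengths, n_body, n_flank, flank_bp) {
  if (nrow(features) == 0L) return(NULL)
  fw <- flank_bp / n_flank
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]
    plus <- features$strand[i] == "+"
    len <- e - s
    body_b <- round(s + (0:n_body) * len / n_body)
    up_b <- round(s - flank_bp + (0:n_flank) * fw)
    dn_b <- round(e + (0:n_flank) * fw)
    if (plus) {
      starts <- c(head(up_b, -1), head(body_b, -1), head(dn_b, -1))
      ends <- c(up_b[-1], body_b[-1], dn_b[-1])
      idx <- seq_len(2L * n_flank + n_body)
    } else {
      ## transcript 5' flank sits genomically right of the gene
      starts <- c(head(dn_b, -1), head(body_b, -1), head(up_b, -1))
      ends <- c(dn_b[-1], body_b[-1], up_b[-1])
      idx <- c(rev(seq_len(n_flank)),
               n_flank + rev(seq_len(n_body)),
               n_flank + n_body + rev(seq_len(n_flank)))
    }
    out[[i]] <- data.table(feature_id = features$feature_id[i],
                           chrom = features$chrom[i],
                           start = as.integer(starts), end = as.integer(ends),
                           bin = idx)
  }
  bins <- rbindlist(out)
  bins[, start := pmax(start, 0L)]
  bins[, end := pmin(end, as.integer(chrom_lengths[chrom]))]
  bins[end > start]
}

## count-weighted pooling of site levels into bins; returns one row per
## (grouping columns x context x bin)
pool_levels <- function(levels, bins, extra_by = character()) {
  if (is.null(bins) || nrow(bins) == 0L) return(NULL)
  lv <- levels[, .(chrom, pos0 = pos - 1L, context, count_m, count_u)]
  b <- copy(bins)[, end := end - 1L]          # inclusive for foverlaps
  setkey(b, chrom, start, end)
  q <- lv[, .(chrom, start = pos0, end = pos0)]
  hits <- foverlaps(q, b, type = "within", nomatch = NULL, which = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  j <- cbind(lv[hits$xid], b[hits$yid, !c("chrom", "start", "end")])
  j[, .(level = weighted_level(count_m, count_u),
        n_sites = .N, reads = sum(as.numeric(count_m + count_u))),
    by = c(extra_by, "context", "bin")]
}

#' Gene or TE metaprofile
#'
#' Bodies are proportionally divided into 20 bins and the 2-kb flanks into
#' 20 fixed 100-bp bins, oriented 5' to 3' (bins 1-20 upstream flank, 21-40
#' body, 41-60 downstream flank; TEs without strand run on the plus
#' convention). Per-bin levels are count-weighted pools over all features.
#' Features with a body shorter than `n_body_bins` bp are skipped and
#' tallied in the `n_skipped` attribute.
#'
#' @param levels a [site_levels()] table.
#' @param annotation a [genome_annotation()].
#' @param feature `"gene"` or `"TE"`.
#' @param config a [pipeline_config()].
#' @param feature_ids optional subset of gene/TE identifiers.
#' @param group label stored in the output's `group` column.
#' @return data.table with `group`, `context`, `zone` (upstream, body,
#'   downstream), `bin` (1..60), `level`, `n_sites`, `reads`; all 60 bins
#'   are present per context (NA level when uncovered).
#' @export
gene_te_profile <- function(levels, annotation, feature = c("gene", "TE"),
                            config = pipeline_config(), feature_ids = NULL,
                            group = feature) {
  feature <- match.arg(feature)
  ft <- if (feature == "gene")
    annotation$genes[, .(feature_id = gene_id, chrom, strand, start, end)]
  else
    annotation$tes[, .(feature_id = te_id, chrom, strand = "+", start, end)]
  if (!is.null(feature_ids)) ft <- ft[feature_id %in% feature_ids]
  n_skip <- sum(ft$end - ft$start < config$n_body_bins)
  ft <- ft[end - start >= config$n_body_bins]
  bins <- feature_profile_bins(ft, annotation$chrom_lengths,
                               config$n_body_bins, config$n_flank_bins,
                               config$flank_bp)
  pooled <- pool_levels(levels, bins)
  total <- 2L * config$n_flank_bins + config$n_body_bins
  full <- CJ(context = CONTEXTS, bin = seq_len(total))
  res <- if (is.null(pooled)) copy(full)[, `:=`(level = NA_real_, n_sites = 0L,
                                                reads = 0)] else
    pooled[full, on = c("context", "bin")]
  res[is.na(n_sites), `:=`(n_sites = 0L, reads = 0)]
  res[, zone := fifelse(bin <= config$n_flank_bins, "upstream",
                        fifelse(bin <= config$n_flank_bins + config$n_body_bins,
                                "body", "downstream"))]
  res[, group := group]
  setcolorder(res, c("group", "context", "zone", "bin", "level", "n_sites", "reads"))
  setorder(res, context, bin)
  data.table::setattr(res, "n_skipped", n_skip)
  res[]
}

#' Exon-only metaprofile stratified by intron count
#'
#' Introns are removed: each gene's exons are concatenated in transcript
#' order into a virtual body which is divided into 20 proportional bins.
#' Genes are grouped by intron count (default groups 0, 1-2, 3-5, >=6) and a
#' 3'-skew statistic, mean of the last 5 bins minus mean of the first 5
#' bins, is reported per group and context.
#'
#' @param levels a [site_levels()] table.
#' @param annotation a [genome_annotation()].
#' @param config a [pipeline_config()] (`intron_count_breaks` sets the
#'   interior group breaks).
#' @return list with `profile` (group x context x bin) and `skew`
#'   (group x context); empty groups keep NA rows.
#' @export
exon_only_profile <- function(levels, annotation, config = pipeline_config()) {
  nb <- config$n_body_bins
  ex <- copy(annotation$exons)
  glab <- intron_count_labels(config$intron_count_breaks)
  if (nrow(ex) == 0L) {
    prof <- CJ(group = glab, context = CONTEXTS, bin = seq_len(nb))[,
      `:=`(level = NA_real_, n_sites = 0L, reads = 0)]
    return(list(profile = prof[],
                skew = CJ(group = glab, context = CONTEXTS)[, skew := NA_real_][]))
  }
  setorder(ex, gene_id, exon_rank)
  ex[, len := end - start]
  ex[, offset := cumsum(c(0L, head(len, -1L))), by = gene_id]
  ex[, body_len := sum(len), by = gene_id]
  ex[, n_introns := .N - 1L, by = gene_id]
  ex[, group := cut_intron_count(n_introns, config$intron_count_breaks)]

  lv <- levels[, .(chrom, pos0 = pos - 1L, context, count_m, count_u)]
  b <- ex[, .(gene_id, chrom, strand, start, end = end - 1L, offset,
              body_len, group)]
  setkey(b, chrom, start, end)
  q <- lv[, .(chrom, start = pos0, end = pos0)]
  hits <- foverlaps(q, b, type = "within", nomatch = NULL, which = TRUE)
  pooled <- NULL
  if (nrow(hits)) {
    j <- cbind(lv[hits$xid], b[hits$yid, .(strand, start, end, offset, body_len, group)])
    j[, vpos := fifelse(strand == "+", offset + (pos0 - start),
                        offset + (end - pos0))]
    j[, bin := pmin(nb, (vpos * nb) %/% body_len + 1L)]
    pooled <- j[, .(level = weighted_level(count_m, count_u), n_sites = .N,
                    reads = sum(as.numeric(count_m + count_u))),
                by = .(group, context, bin)]
  }
  full <- CJ(group = glab, context = CONTEXTS, bin = seq_len(nb))
  prof <- if (is.null(pooled)) copy(full)[, `:=`(level = NA_real_, n_sites = 0L,
                                                 reads = 0)] else {
    pooled[, group := as.character(group)]
    pooled[full, on = c("group", "context", "bin")]
  }
  prof[is.na(n_sites), `:=`(n_sites = 0L, reads = 0)]
  setorder(prof, group, context, bin)
  k <- 5L
  skew <- prof[, .(skew = mean(level[bin > nb - k], na.rm = TRUE) -
                     mean(level[bin <= k], na.rm = TRUE)),
               by = .(group, context)]
  skew[is.nan(skew), skew := NA_real_]
  list(profile = prof[], skew = skew[])
}

intron_count_labels <- function(breaks) {
  lo <- c(0L, breaks + 1L)
  hi <- c(breaks, Inf)
  fifelse(lo == hi, as.character(lo),
          fifelse(is.infinite(hi), paste0(">=", lo), paste0(lo, "-", hi)))
}

cut_intron_count <- function(n, breaks) {
  labs <- intron_count_labels(breaks)
  idx <- findInterval(n, c(0, breaks + 1)) # 1..length(labs)
  labs[idx]
}

#' Intron-length-stratified intron/exon panels
#'
#' Introns are grouped by length (default <=1 kb, 1-5 kb, 5-20 kb, >20 kb)
#' and by ordinal (first, second, third intron in transcript orientation).
#' Each panel profiles the upstream flanking exon (5 proportional bins), the
#' intron (10 bins) and the downstream flanking exon (5 bins), bins running
#' 5' to 3'. Pooling is count-weighted; empty panels keep NA rows.
#'
#' @param levels a [site_levels()] table.
#' @param annotation a [genome_annotation()].
#' @param config a [pipeline_config()].
#' @param max_ordinal largest intron ordinal profiled.
#' @return data.table with `len_group`, `intron_rank`, `context`, `zone`
#'   (exon_up, intron, exon_down), `bin`, `level`, `n_sites`, `reads`.
#' @export
intron_length_profiles <- function(levels, annotation, config = pipeline_config(),
                                   max_ordinal = 3L) {
  nb_i <- config$intron_bins
  nb_e <- config$exon_bins
  brk <- config$intron_length_breaks
  glab <- c(paste0("<=", brk[1] / 1000, "kb"),
            paste0(brk[1] / 1000, "-", brk[2] / 1000, "kb"),
            paste0(brk[2] / 1000, "-", brk[3] / 1000, "kb"),
            paste0(">", brk[3] / 1000, "kb"))
  ir <- introns(annotation)
  full <- CJ(len_group = glab, intron_rank = seq_len(max_ordinal),
             context = CONTEXTS, bin = seq_len(nb_i + 2L * nb_e))
  empty <- function() copy(full)[, `:=`(level = NA_real_, n_sites = 0L, reads = 0)]
  if (nrow(ir) == 0L) return(finish_panel(empty(), nb_e, nb_i))
  ir <- ir[intron_rank <= max_ordinal]
  ir[, intron_len := end - start]
  ir[, len_group := glab[findInterval(intron_len, c(0, brk + 1))]]

  ex <- annotation$exons
  bins_list <- vector("list", nrow(ir))
  for (i in seq_len(nrow(ir))) {
    g <- ir$gene_id[i]; plus <- ir$strand[i] == "+"; rk <- ir$intron_rank[i]
    gex <- ex[gene_id == g]
    ex_up <- gex[exon_rank == rk]     # exon 5' of the intron
    ex_dn <- gex[exon_rank == rk + 1L]
    part <- function(s, e, n, zone) {
      bdy <- round(s + (0:n) * (e - s) / n)
      idx <- if (plus) seq_len(n) else rev(seq_len(n))
      data.table(chrom = ir$chrom[i], start = as.integer(head(bdy, -1)),
                 end = as.integer(bdy[-1]), zone = zone, zbin = idx)
    }
    ## ex_up/ex_dn are picked by transcript rank, so the zone labels are
    ## already transcript-oriented on both strands
    pieces <- rbind(part(ex_up$start, ex_up$end, nb_e, "exon_up"),
                    part(ir$start[i], ir$end[i], nb_i, "intron"),
                    part(ex_dn$start, ex_dn$end, nb_e, "exon_down"))
    pieces[, `:=`(len_group = ir$len_group[i], intron_rank = rk)]
    bins_list[[i]] <- pieces
  }
  bins <- rbindlist(bins_list)
  bins <- bins[end > start]
  bins[, bin := fifelse(zone == "exon_up", zbin,
                        fifelse(zone == "intron", nb_e + zbin,
                                nb_e + nb_i + zbin))]
  pooled <- pool_levels(levels, bins[, .(chrom, start, end, bin, len_group,
                                         intron_rank)],
                        extra_by = c("len_group", "intron_rank"))
  res <- if (is.null(pooled)) empty() else
    pooled[full, on = c("len_group", "intron_rank", "context", "bin")]
  res[is.na(n_sites), `:=`(n_sites = 0L, reads = 0)]
  finish_panel(res, nb_e, nb_i)
}

finish_panel <- function(res, nb_e, nb_i) {
  res[, zone := fifelse(bin <= nb_e, "exon_up",
                        fifelse(bin <= nb_e + nb_i, "intron", "exon_down"))]
  setorder(res, len_group, intron_rank, context, bin)
  setcolorder(res, c("len_group", "intron_rank", "context", "zone", "bin",
                     "level", "n_sites", "reads"))
  res[]
}

#' Per-gene methylation of standard region classes
#'
#' For each gene and context: upstream and downstream 500/1000/2000 bp
#' (strand-aware, clipped at chromosome bounds), exon, intron and
#' exon+intron (gene body) count-weighted levels. Genes without introns get
#' an NA intron level; regions without covered sites are NA.
#'
#' @param levels a [site_levels()] table.
#' @param annotation a [genome_annotation()].
#' @param config a [pipeline_config()].
#' @return data.table with `gene_id`, `region`, `context`, `level`,
#'   `n_sites`, `reads`.
#' @export
region_methylation <- function(levels, annotation, config = pipeline_config()) {
  g <- annotation$genes
  regions <- c("up500", "up1000", "up2000", "exon", "intron", "body",
               "down500", "down1000", "down2000")
  if (nrow(g) == 0L)
    return(CJ(gene_id = character(), region = regions, context = CONTEXTS))
  ivs <- list()
  for (w in c(500L, 1000L, 2000L)) {
    ivs[[paste0("up", w)]] <- gene_flanks(annotation, w, "up")
    ivs[[paste0("down", w)]] <- gene_flanks(annotation, w, "down")
  }
  ivs[["exon"]] <- annotation$exons[, .(gene_id, chrom, start, end)]
  ivs[["intron"]] <- introns(annotation)[, .(gene_id, chrom, start, end)]
  ivs[["body"]] <- g[, .(gene_id, chrom, start, end)]
  all_iv <- rbindlist(lapply(names(ivs), function(nm)
    ivs[[nm]][, .(gene_id, chrom, start, end, region = nm)]), use.names = TRUE)
  lv <- levels[, .(chrom, pos0 = pos - 1L, context, count_m, count_u)]
  b <- copy(all_iv)[, end := end - 1L]
  setkey(b, chrom, start, end)
  q <- lv[, .(chrom, start = pos0, end = pos0)]
  hits <- foverlaps(q, b, type = "within", nomatch = NULL, which = TRUE)
  pooled <- NULL
  if (nrow(hits)) {
    j <- cbind(lv[hits$xid], b[hits$yid, .(gene_id, region)])
    pooled <- j[, .(level = weighted_level(count_m, count_u), n_sites = .N,
                    reads = sum(as.numeric(count_m + count_u))),
                by = .(gene_id, region, context)]
  }
  full <- CJ(gene_id = g$gene_id, region = regions, context = CONTEXTS)
  res <- if (is.null(pooled)) copy(full)[, `:=`(level = NA_real_, n_sites = 0L,
                                                reads = 0)] else
    pooled[full, on = c("gene_id", "region", "context")]
  res[is.na(n_sites), `:=`(n_sites = 0L, reads = 0)]
  setorder(res, gene_id, region, context)
  res[]
}
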