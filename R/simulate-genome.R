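#' Generate a synthetic genome with gene models and TE intervals
#'
#' Builds random chromosome sequences, places gene models sequentially with
#' intergenic gaps, draws intron lengths from a short/long/ultra-long
#' mixture (a configurable fraction exceeds 5 kb and 20 kb, mimicking
#' conifer-style gene architecture), and inserts transposable elements into
#' non-exonic space with a strong preference for long introns until the
#' target TE fraction of the genome is reached. Age-marker genes receive a
#' forced long first intron so that a marker segment spanning the upstream
#' region, first exon and the 5' end of that intron fits inside them.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a [genome_annotation()]). Marker genes are flagged in
#'   `annotation$genes$is_marker`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    chrom_len <- rep(as.integer(config$chrom_length_bp), config$n_chromosomes)
    names(chrom_len) <- paste0("chr", seq_len(config$n_chromosomes))

    seqs <- lapply(chrom_len, function(n)
      paste(sample(names(config$base_composition), n, replace = TRUE,
                   prob = config$base_composition), collapse = ""))

    genes <- gene_list <- exon_list <- NULL
    n_genes <- config$n_genes
    marker_idx <- integer()
    if (n_genes > 0L && config$n_marker_genes > 0L)
      marker_idx <- unique(round(seq(1, n_genes,
                                     length.out = min(config$n_marker_genes, n_genes))))
    gene_rows <- vector("list", n_genes)
    exon_rows <- vector("list", n_genes)
    chrom_i <- 1L
    cursor <- as.integer(runif(1, 2600, 4000))
    end_buffer <- 2600L
    i <- 1L
    while (i <= n_genes) {
      is_marker <- i %in% marker_idx
      n_ex <- sample(seq(config$exons_per_gene_range[1],
                         config$exons_per_gene_range[2]), 1L)
      if (is_marker) n_ex <- max(n_ex, 2L)
      ex_len <- pmin(pmax(round(rlnorm(n_ex, config$exon_length_meanlog,
                                       config$exon_length_sdlog)), 60L), 1500L)
      in_len <- integer(0)
      if (n_ex > 1L) {
        u <- runif(n_ex - 1L)
        in_len <- ifelse(
          u < config$intron_frac_20kb,
          round(runif(n_ex - 1L, 20001, 35000)),
          ifelse(u < config$intron_frac_20kb + config$intron_frac_5kb,
                 round(runif(n_ex - 1L, 5001, 20000)),
                 pmin(pmax(round(rlnorm(n_ex - 1L, config$intron_length_meanlog,
                                        config$intron_length_sdlog)), 80L), 5000L)))
      }
      strand <- sample(c("+", "-"), 1L)
      if (is_marker) {
        ## the first intron in transcript orientation must host the marker
        ## segment end-to-end
        need <- config$marker_intron_span_bp + 1000L
        k <- if (strand == "+") 1L else n_ex - 1L
        in_len[k] <- max(in_len[k], need)
      }
      span <- sum(ex_len) + sum(in_len)
      if (cursor + span + end_buffer > chrom_len[chrom_i]) {
        chrom_i <- chrom_i + 1L
        if (chrom_i > length(chrom_len))
          stop("chromosomes too short to host the requested genes; ",
               "increase chrom_length_bp or reduce n_genes", call. = FALSE)
        cursor <- as.integer(runif(1, 2600, 4000))
        next
      }
      gid <- sprintf("g%04d", i)
      starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      gene_rows[[i]] <- data.table(
        gene_id = gid, chrom = names(chrom_len)[chrom_i], strand = strand,
        start = cursor, end = cursor + span, is_marker = is_marker)
      exon_rows[[i]] <- data.table(
        gene_id = gid, chrom = names(chrom_len)[chrom_i], strand = strand,
        start = as.integer(starts), end = as.integer(ends), exon_rank = rank)
      cursor <- as.integer(cursor + span +
                             runif(1, config$intergenic_gap_range[1],
                                   config$intergenic_gap_range[2]))
      i <- i + 1L
    }
    genes <- if (n_genes > 0L) rbindlist(gene_rows) else
      data.table(gene_id = character(), chrom = character(), strand = character(),
                 start = integer(), end = integer(), is_marker = logical())
    exons <- if (n_genes > 0L) rbindlist(exon_rows) else
      data.table(gene_id = character(), chrom = character(), strand = character(),
                 start = integer(), end = integer(), exon_rank = integer())

    tes <- place_tes(chrom_len, genes, exons, config)

    ann <- genome_annotation(chrom_len, genes, exons, tes)
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(chrom_len)
    list(genome = genome, annotation = ann)
  })
}

## Fill non-exonic space with TEs until the target fraction of the genome is
## covered. Insertable intervals are weighted (long introns first) and filled
## left to right with exponential gaps, which yields realistic nested-looking
## high occupancy inside long introns.
place_tes <- function(chrom_len, genes, exons, config) {
  empty <- data.table(te_id = character(), chrom = character(),
                      start = integer(), end = integer(), te_class = character())
  target <- config$te_fraction * sum(chrom_len)
  if (target <= 0) return(empty)

  ## non-exonic intervals per chromosome
  ivs <- rbindlist(lapply(names(chrom_len), function(ch) {
    ex <- exons[chrom == ch][order(start)]
    bounds <- c(0L, as.vector(rbind(ex$start, ex$end)), chrom_len[[ch]])
    s <- bounds[seq(1, length(bounds), 2)]
    e <- bounds[seq(2, length(bounds), 2)]
    data.table(chrom = ch, start = as.integer(s), end = as.integer(e))
  }))
  ivs <- ivs[end - start >= 150L]
  ## classify: long intron, short intron, intergenic
  intr <- introns(genome_annotation(chrom_len, genes, exons, empty))
  ivs[, class := "intergenic"]
  if (nrow(intr)) {
    hit <- overlap_first(data.table(chrom = ivs$chrom,
                                    pos0 = as.integer((ivs$start + ivs$end) / 2)),
                         intr)
    ivs[!is.na(hit), class := fifelse(
      (intr$end - intr$start)[hit[!is.na(hit)]] > 5000L, "long_intron",
      "short_intron")]
  }
  w <- c(long_intron = 4, intergenic = 1, short_intron = 0.5)
  gap_mean <- c(long_intron = 250, intergenic = 600, short_intron = 900)
  ord <- sample(nrow(ivs), prob = w[ivs$class] * (ivs$end - ivs$start))
  te_classes <- c("LTR/Gypsy", "LTR/Copia", "DNA", "LINE")

  placed <- 0
  rows <- list()
  for (j in ord) {
    if (placed >= target) break
    lo <- ivs$start[j]; hi <- ivs$end[j]; cls <- ivs$class[j]
    cur <- lo + round(rexp(1, 1 / gap_mean[[cls]]))
    while (cur < hi - 120L && placed < target) {
      len <- min(max(round(rlnorm(1, log(1500), 0.8)), 100L), 8000L)
      e <- min(cur + len, hi)
      rows[[length(rows) + 1L]] <- data.table(
        chrom = ivs$chrom[j], start = as.integer(cur), end = as.integer(e),
        te_class = sample(te_classes, 1L, prob = c(0.5, 0.3, 0.1, 0.1)))
      placed <- placed + (e - cur)
      cur <- e + round(rexp(1, 1 / gap_mean[[cls]]))
    }
  }
  if (!length(rows)) return(empty)
  tes <- rbindlist(rows)
  setorder(tes, chrom, start)
  tes[, te_id := sprintf("te%05d", .I)]
  setcolorder(tes, c("te_id", "chrom", "start", "end", "te_class"))
  tes[]
}
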