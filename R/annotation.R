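#' Construct a genome annotation
#'
#' Container for chromosome lengths, gene models with exon structure, and
#' transposable-element intervals. All coordinates are 0-based half-open;
#' exon ranks follow transcript (5' to 3') orientation.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param genes data.table with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (and optionally `is_marker`).
#' @param exons data.table with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank`.
#' @param tes data.table with columns `te_id`, `chrom`, `start`, `end`,
#'   `te_class`.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_lengths, genes, exons, tes) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  tes <- as.data.table(tes)
  if (nrow(genes)) {
    if (!"is_marker" %in% names(genes)) genes[, is_marker := FALSE]
    bad <- genes[!(chrom %in% names(chrom_lengths)) | start < 0 |
                   end > chrom_lengths[chrom] | end <= start]
    if (nrow(bad)) stop("gene intervals outside chromosome bounds", call. = FALSE)
  }
  if (nrow(exons)) {
    j <- merge(exons, genes[, .(gene_id, gstart = start, gend = end)], by = "gene_id")
    if (any(j$start < j$gstart | j$end > j$gend))
      stop("exons outside gene bounds", call. = FALSE)
    ov <- exons[order(gene_id, start),
                .(bad = any(start[-1] < end[-.N])), by = gene_id]
    if (nrow(exons) > nrow(genes) && any(ov$bad, na.rm = TRUE))
      stop("overlapping exons within a gene", call. = FALSE)
  }
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon))
    stop("genes without exons: ", paste(head(no_exon, 3), collapse = ", "),
         call. = FALSE)
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 exons = exons, tes = tes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %.2f Mb, %d gene(s), %d TE(s)\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(x$genes), nrow(x$tes)))
  invisible(x)
}

#' Derive introns from the exon structure
#'
#' Introns are the gaps between consecutive exons of a gene; `intron_rank`
#' counts from the 5' end of the transcript, so on minus-strand genes the
#' first intron is the genomically last gap.
#'
#' @param annotation a [genome_annotation()].
#' @return data.table with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `intron_rank`.
#' @export
introns <- function(annotation) {
  ex <- annotation$exons[order(gene_id, start)]
  if (nrow(ex) == 0L)
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), intron_rank = integer()))
  ir <- ex[, {
    if (.N < 2L) NULL else {
      s <- end[-.N]; e <- start[-1]
      rk <- if (strand[1] == "+") seq_len(.N - 1L) else rev(seq_len(.N - 1L))
      .(chrom = chrom[1], strand = strand[1], start = s, end = e,
        intron_rank = rk)
    }
  }, by = gene_id]
  if (nrow(ir) == 0L)
    ir <- data.table(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer(), intron_rank = integer())
  ir[]
}

## strand-aware flanks of gene spans; side = "up" or "down"
gene_flanks <- function(annotation, width, side = c("up", "down")) {
  side <- match.arg(side)
  g <- annotation$genes
  if (nrow(g) == 0L)
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer()))
  upstream <- (side == "up")
  fl <- g[, {
    left <- (strand == "+") == upstream     # flank lies left of the gene
    s <- fifelse(left, start - as.integer(width), end)
    e <- fifelse(left, start, end + as.integer(width))
    .(gene_id, chrom, strand, start = s, end = e)
  }]
  ## clip at chromosome bounds
  fl[, start := pmax(start, 0L)]
  fl[, end := pmin(end, as.integer(annotation$chrom_lengths[chrom]))]
  fl[end > start]
}
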