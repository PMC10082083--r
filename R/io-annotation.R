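#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` records (1-based inclusive on disk) and
#' normalizes them to the package-internal 0-based half-open convention.
#' Genes without exon children are skipped with a warning. Chromosome
#' lengths are taken from `##sequence-region` headers when present,
#' otherwise from the supplied fallback.
#'
#' @param path GFF3 file.
#' @param chrom_lengths optional named vector used when the file carries no
#'   sequence-region pragmas.
#' @return a [genome_annotation()] (with an empty TE table).
#' @export
read_gff3 <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(meta$type),
                   id = as.character(meta$ID),
                   parent = vapply(as.list(meta$Parent), function(x)
                     if (length(x)) as.character(x)[1] else NA_character_, ""))
  pragma <- grep("^##sequence-region", readLines(path, n = 500L), value = TRUE)
  if (length(pragma)) {
    parts <- strsplit(trimws(pragma), "\\s+")
    chrom_lengths <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
    names(chrom_lengths) <- vapply(parts, `[`, "", 2)
  } else if (is.null(chrom_lengths)) {
    si <- GenomeInfoDb::seqlengths(gr)
    chrom_lengths <- if (!all(is.na(si))) si[!is.na(si)] else
      vapply(split(dt$end, dt$chrom), max, numeric(1))
  }

  genes <- dt[type == "gene", .(gene_id = id, chrom, strand, start, end)]
  exons <- dt[type == "exon", .(gene_id = parent, chrom, strand, start, end)]
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) {
    warning(sprintf("skipping %d gene(s) without exons", length(no_exon)))
    genes <- genes[!gene_id %in% no_exon]
  }
  exons <- exons[gene_id %in% genes$gene_id]
  setorder(exons, gene_id, start)
  exons[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
        by = gene_id]
  empty_te <- data.table(te_id = character(), chrom = character(),
                         start = integer(), end = integer(), te_class = character())
  genome_annotation(chrom_lengths, genes, exons, empty_te)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` record per gene and `exon` children with `Parent`
#' attributes, converting internal 0-based half-open coordinates back to the
#' 1-based inclusive convention of GFF3.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- copy(annotation$exons)
  setorder(e, gene_id, start)
  e[, id := sprintf("%s.exon%d", gene_id, seq_len(.N)), by = gene_id]
  mk <- function(dt, type, ids, parents) {
    gr <- GenomicRanges::GRanges(
      dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end), strand = dt$strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- ids
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
      lapply(parents, function(p) if (is.na(p)) character(0) else p))
    gr
  }
  grs <- c(mk(g, "gene", g$gene_id, NA_character_),
           mk(e, "exon", e$id, e$gene_id))
  GenomeInfoDb::seqlengths(grs) <-
    annotation$chrom_lengths[GenomeInfoDb::seqlevels(grs)]
  rtracklayer::export(sort(grs), path, format = "gff3")
  ## rtracklayer omits sequence-region pragmas; insert them by hand
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", names(annotation$chrom_lengths),
                    as.integer(annotation$chrom_lengths))
  writeLines(c(lines[1], pragma, lines[-1]), path)
  invisible(path)
}

#' Read intervals from BED
#'
#' BED is 0-based half-open on disk, which matches the internal convention,
#' so coordinates pass through unchanged. Zero- or negative-length intervals
#' are rejected.
#'
#' @param path BED file (3-6 columns).
#' @return data.table with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  meta <- S4Vectors::mcols(gr)
  if (!is.null(meta$name)) dt[, name := meta$name]
  if (!is.null(meta$score)) dt[, score := as.numeric(meta$score)]
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) dt[, strand := st]
  if (any(dt$end <= dt$start))
    stop("BED interval with end <= start", call. = FALSE)
  dt[]
}

#' Write intervals to BED
#'
#' @param intervals data.table with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$end <= intervals$start))
    stop("BED interval with end <= start", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*")
  if ("name" %in% names(intervals)) S4Vectors::mcols(gr)$name <- intervals$name
  if ("score" %in% names(intervals)) S4Vectors::mcols(gr)$score <- intervals$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read or write a bedGraph density track
#'
#' @param path bedGraph file.
#' @return data.table with `chrom`, `start` (0-based), `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = S4Vectors::mcols(gr)$score)
}

#' @rdname read_bedgraph
#' @param track data.table with `chrom`, `start`, `end`, `score`.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  S4Vectors::mcols(gr)$score <- track$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
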