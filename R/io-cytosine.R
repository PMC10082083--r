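#' Read a cytosine report
#'
#' Reads the Bismark-style per-cytosine report dialect: a headerless TSV
#' with columns chromosome, 1-based position, strand, methylated count,
#' unmethylated count, context and trinucleotide sub-context. Rows are
#' validated (positive positions, non-negative counts, sub-context starting
#' with C and consistent with the context column); the first offending line
#' number is reported on failure. When a genome is supplied, contexts are
#' re-derived from the sequence and mismatches are reported via the
#' `n_context_mismatch` attribute.
#'
#' @param path input TSV (optionally gzipped).
#' @param genome optional DNAStringSet or named character vector.
#' @return data.table with columns `chrom`, `pos`, `strand`, `count_m`,
#'   `count_u`, `context`, `subcontext`.
#' @export
read_cytosine_report <- function(path, genome = NULL) {
  cols <- c("chrom", "pos", "strand", "count_m", "count_u", "context", "subcontext")
  empty <- data.table(chrom = character(), pos = integer(), strand = character(),
                      count_m = integer(), count_u = integer(),
                      context = character(), subcontext = character())
  if (file.exists(path) && file.size(path) == 0) return(empty)
  tbl <- fread(path, sep = "\t", header = FALSE,
               colClasses = list(character = c(1, 3, 6, 7), integer = c(2, 4, 5)))
  if (nrow(tbl) == 0L) return(empty)
  if (ncol(tbl) != 7L)
    stop(sprintf("expected 7 columns in cytosine report, found %d", ncol(tbl)),
         call. = FALSE)
  setnames(tbl, cols)
  fail_at <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      ln <- which(cond | is.na(cond))[1]
      stop(sprintf("%s at line %d of %s", what, ln, path), call. = FALSE)
    }
  }
  fail_at(tbl$pos < 1L, "non-positive position")
  fail_at(tbl$count_m < 0L | tbl$count_u < 0L, "negative count")
  fail_at(!tbl$strand %in% c("+", "-"), "invalid strand")
  fail_at(substr(tbl$subcontext, 1, 1) != "C", "sub-context not starting with C")
  fail_at(tbl$context != context_from_subcontext(tbl$subcontext),
          "context inconsistent with sub-context")
  if (!is.null(genome)) {
    gnames <- if (inherits(genome, "DNAStringSet")) names(genome) else names(genome)
    unknown <- setdiff(unique(tbl$chrom), gnames)
    if (length(unknown))
      stop("chromosomes absent from genome: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    ref <- classify_contexts(genome)
    chk <- ref[tbl, on = c("chrom", "pos", "strand")]
    n_bad <- sum(is.na(chk$context) | chk$context != chk$i.context)
    if (n_bad > 0)
      warning(sprintf("%d site(s) disagree with genome-derived contexts", n_bad))
    data.table::setattr(tbl, "n_context_mismatch", n_bad)
  }
  tbl[]
}

#' Write a cytosine report
#'
#' @param table a cytosine site table (see [read_cytosine_report()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(table, path) {
  fwrite(table[, .(chrom, pos, strand, count_m, count_u, context, subcontext)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
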