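#' Classify every cytosine of a genome by strand, context and sub-context
#'
#' Scans both strands: a plus-strand cytosine is read with its two downstream
#' bases, a minus-strand cytosine (a G on the reference) is read on the
#' reverse complement. Contexts follow the plant convention (CG when the next
#' base is G, CHG when base three is G, CHH otherwise; H = A, C or T), giving
#' 4 CG, 3 CHG and 9 CHH trinucleotide sub-contexts. Cytosines within 2 bp of
#' a chromosome end are excluded, and trinucleotides containing an ambiguous
#' base (N) are dropped and tallied in the `n_ambiguous` attribute.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector of
#'   chromosome sequences.
#' @return data.table with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `subcontext`, ordered by chromosome and position.
#' @export
classify_contexts <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- vector("list", length(genome))
  n_amb <- 0L
  for (k in seq_along(genome)) {
    s <- strsplit(toupper(genome[[k]]), "", fixed = TRUE)[[1]]
    n <- length(s)
    if (n < 3L) next
    ## plus strand: C at i read with bases i+1, i+2, so the last two
    ## positions of the chromosome cannot be classified
    ip <- which(s == "C")
    ip <- ip[ip <= n - 2L]
    ## minus strand: G at i, trinucleotide = complement of s[i], s[i-1],
    ## s[i-2]; the first two positions cannot be classified
    im <- which(s == "G")
    im <- im[im >= 3L]
    subp <- paste0(s[ip], s[ip + 1L], s[ip + 2L])
    subm <- paste0(comp[s[im]], comp[s[im - 1L]], comp[s[im - 2L]])
    dt <- data.table(
      chrom = names(genome)[k],
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      subcontext = c(subp, subm))
    amb <- grepl("N", dt$subcontext, fixed = TRUE)
    n_amb <- n_amb + sum(amb)
    dt <- dt[!amb]
    dt[, context := context_from_subcontext(subcontext)]
    out[[k]] <- dt
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(chrom = character(), pos = integer(), strand = character(),
                      subcontext = character(), context = character())
  setorder(res, chrom, pos, strand)
  setcolorder(res, c("chrom", "pos", "strand", "context", "subcontext"))
  data.table::setattr(res, "n_ambiguous", n_amb)
  res[]
}
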