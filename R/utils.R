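## Small shared helpers. All genomic intervals inside the package are
## 0-based half-open [start, end); positions in cytosine reports are 1-based.

CONTEXTS <- c("CG", "CHG", "CHH")

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#'
#' @param seed master integer seed.
#' @param k integer offset identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483646) + 1L
}

#' Count-weighted methylation level
#'
#' The weighted methylation level of a set of cytosines is the sum of
#' methylated read counts divided by the sum of total read counts, not a
#' mean of per-site ratios.
#'
#' @param m methylated read counts.
#' @param u unmethylated read counts.
#' @return a ratio in `[0, 1]`, or `NA` when no reads are present.
#' @export
weighted_level <- function(m, u) {
  tot <- sum(as.numeric(m)) + sum(as.numeric(u))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(m)) / tot
}

## context implied by a trinucleotide starting with C
context_from_subcontext <- function(sub) {
  b2 <- substr(sub, 2, 2)
  b3 <- substr(sub, 3, 3)
  fifelse(b2 == "G", "CG", fifelse(b3 == "G", "CHG", "CHH"))
}

## point-in-interval overlap join; returns for each query row the index of
## the first matching interval in `ivs` (NA when none). Both data.tables use
## 0-based half-open coordinates with columns chrom, start, end.
overlap_first <- function(points, ivs) {
  if (nrow(ivs) == 0L || nrow(points) == 0L)
    return(rep(NA_integer_, nrow(points)))
  q <- data.table(chrom = points$chrom, start = points$pos0,
                  end = points$pos0 + 1L, xid = seq_len(nrow(points)))
  iv <- data.table(chrom = ivs$chrom, start = ivs$start, end = ivs$end,
                   ivid = seq_len(nrow(ivs)))
  ## half-open: overlap requires point in [start, end-1] inclusive
  iv[, end := end - 1L]
  q[, end := end - 1L]
  setkey(iv, chrom, start, end)
  hits <- foverlaps(q, iv, type = "within", nomatch = NA, mult = "first")
  out <- rep(NA_integer_, nrow(points))
  out[hits$xid] <- hits$ivid
  out
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
}
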