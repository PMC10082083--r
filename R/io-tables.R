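#' Read a TPM expression table
#'
#' Expects a TSV with a `gene_id` column and one TPM column per sample.
#' When a sample sheet is supplied, every sheet sample must be present.
#'
#' @param path TSV file.
#' @param sample_sheet optional sheet from [read_sample_sheet()].
#' @return data.table, genes in rows.
#' @export
read_tpm_table <- function(path, sample_sheet = NULL) {
  tbl <- fread(path, sep = "\t")
  if (!"gene_id" %in% names(tbl))
    stop("TPM table needs a 'gene_id' column", call. = FALSE)
  num <- setdiff(names(tbl), "gene_id")
  if (any(vapply(tbl[, ..num], function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("negative TPM values", call. = FALSE)
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample_id, names(tbl))
    if (length(missing))
      stop("samples missing from TPM table: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  tbl
}

#' @rdname read_tpm_table
#' @param table TPM data.table.
#' @export
write_tpm_table <- function(table, path) {
  fwrite(table, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `age_years`, `replicate`; the
#' (age, replicate) pairs must be unique.
#'
#' @param path TSV file.
#' @return data.table sample sheet.
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path, sep = "\t",
                 colClasses = list(character = "sample_id",
                                   integer = c("age_years", "replicate")))
  need <- c("sample_id", "age_years", "replicate")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet[, .(age_years, replicate)]))
    stop("duplicated (age, replicate) pair in sample sheet", call. = FALSE)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.table.
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(sheet[, .(sample_id, age_years, replicate)], path, sep = "\t")
  invisible(path)
}

#' Read or write simulation ground truth as JSON
#'
#' @param path JSON file.
#' @return ground-truth list with data.table elements.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, function(x) if (is.data.frame(x)) as.data.table(x) else x)
}

#' @rdname read_ground_truth
#' @param ground_truth list as produced by [simulate_methylation_states()].
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write analysis result tables to a directory
#'
#' DMR records go to a BED-like TSV (0-based half-open bins with context,
#' comparison, levels, difference, p, adjusted p and direction); profile
#' tables go to tidy TSVs; a `run_info.json` log records the effective
#' configuration, its hash and the seed.
#'
#' @param results named list of data.tables; names become file stems.
#' @param outdir output directory (created if absent).
#' @param config optional configuration to log.
#' @param seed optional seed to log.
#' @return invisible character vector of the files written.
#' @export
write_results <- function(results, outdir, config = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(results)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    fwrite(results[[nm]], f, sep = "\t")
    files <- c(files, f)
  }
  info <- list(written = basename(files), time = format(Sys.time()))
  if (!is.null(config)) {
    info$config <- unclass(config)
    info$config_hash <- config_hash(config)
  }
  if (!is.null(seed)) info$seed <- seed
  jf <- file.path(outdir, "run_info.json")
  jsonlite::write_json(info, jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, jf))
}

#' Hash of a configuration object
#'
#' A short deterministic fingerprint of the effective configuration, logged
#' with every result set.
#'
#' @param config any configuration object.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  ## fold the serialized bytes into a 48-bit fingerprint
  v <- as.integer(raw)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2^40
  sprintf("%05x%05x", as.integer(h %/% 2^20), as.integer(h %% 2^20))
}
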