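# Readers/writers for the pipeline's plain-text interchange formats.

#' Read a parcel time-series TSV (T rows x P parcels, header row)
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_parcel_tsv <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Read a BIDS-style events TSV (`onset`, `duration`, `value`)
#' @param path file path.
#' @return Data frame.
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path)
  need <- c("onset", "value")
  if (!all(need %in% names(ev))) {
    stop(sprintf("events file %s lacks columns: %s", path,
                 paste(setdiff(need, names(ev)), collapse = ", ")), call. = FALSE)
  }
  ev
}

#' Read the subject covariates TSV
#' @param path file path.
#' @return Data frame with one row per subject.
#' @export
read_covariates_tsv <- function(path) {
  cv <- read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(cv)) stop("covariates need a `subject_id` column", call. = FALSE)
  cv
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  path
}
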