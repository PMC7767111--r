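#' Multi-lead ECG/VCG record
#'
#' The canonical signal container of the package: a set of named,
#' equal-length, real-valued leads sampled at a common rate.  Amplitudes
#' are in millivolt unless a source file header states otherwise.
#'
#' @param signals numeric matrix, one column per lead, one row per sample;
#'   column names are the lead names (e.g. `"i"`, `"vx"`, `"vy"`, `"vz"`).
#'   A named list of equal-length numeric vectors is also accepted.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param record_id character identifier for the record.
#' @return An object of class `multi_lead_record`: a list with elements
#'   `record_id`, `sampling_rate` and `signals` (numeric matrix with lead
#'   names as column names).
#' @export
multi_lead_record <- function(signals, sampling_rate, record_id = "record") {
  if (is.list(signals) && !is.data.frame(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) > 1L)
      stop("all leads must have equal length (got ", paste(lens, collapse = ", "), ")")
    signals <- do.call(cbind, lapply(signals, as.numeric))
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (ncol(signals) < 1L) stop("a record needs at least one lead")
  if (is.null(colnames(signals)) || anyNA(colnames(signals)) ||
      any(colnames(signals) == ""))
    stop("every lead must be named")
  if (anyDuplicated(tolower(colnames(signals))))
    stop("lead names must be unique (case-insensitive)")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(
    list(record_id = as.character(record_id)[1L],
         sampling_rate = as.numeric(sampling_rate),
         signals = signals),
    class = "multi_lead_record")
}

#' @export
print.multi_lead_record <- function(x, ...) {
  cat("<multi_lead_record> ", x$record_id, "\n",
      "  leads:    ", paste(colnames(x$signals), collapse = ", "), "\n",
      "  samples:  ", nrow(x$signals),
      sprintf(" (%.2f s at %g Hz)\n", nrow(x$signals) / x$sampling_rate,
              x$sampling_rate), sep = "")
  invisible(x)
}

#' Lead names of a record
#' @param record a `multi_lead_record`.
#' @return character vector of lead names in storage order.
#' @export
lead_names <- function(record) colnames(record$signals)

#' Extract one lead as a numeric vector
#'
#' Lead lookup is case-insensitive, following PTB naming conventions.
#'
#' @param record a `multi_lead_record`.
#' @param name lead name.
#' @return numeric vector of samples.
#' @export
get_lead <- function(record, name) {
  idx <- match_lead(record, name)
  record$signals[, idx]
}

#' Select a subset of leads (case-insensitive), preserving request order
#' @param record a `multi_lead_record`.
#' @param names character vector of lead names.
#' @return a `multi_lead_record` with the requested leads.
#' @export
select_leads <- function(record, names) {
  idx <- vapply(names, function(nm) match_lead(record, nm), integer(1L))
  multi_lead_record(record$signals[, idx, drop = FALSE],
                    record$sampling_rate, record$record_id)
}

match_lead <- function(record, name) {
  have <- colnames(record$signals)
  idx <- match(tolower(name), tolower(have))
  if (is.na(idx))
    stop("unknown lead '", name, "'; available leads: ",
         paste(have, collapse = ", "))
  idx
}

n_samples <- function(record) nrow(record$signals)

#' Replace the signal matrix of a record, keeping id
#' @noRd
with_signals <- function(record, signals, sampling_rate = record$sampling_rate) {
  multi_lead_record(signals, sampling_rate, record$record_id)
}
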