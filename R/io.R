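#' Write a record to WFDB format (.hea / .dat, format 16)
#'
#' Writes a minimal two-file WFDB record: a text header and a single
#' interleaved 16-bit little-endian signal file.  Amplitudes are
#' quantized with the given gain (ADC units per mV).
#'
#' @param record a `multi_lead_record`.
#' @param path record path without extension; `path.hea` and `path.dat`
#'   are created.
#' @param gain ADC units per mV (default 2000, i.e. 0.5 uV resolution).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 2000) {
  sig <- record$signals
  n <- nrow(sig)
  adc <- round(sig * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds 16-bit range at gain ", gain)
  storage.mode(adc) <- "integer"
  base <- basename(path)
  checksum <- vapply(seq_len(ncol(adc)), function(j) {
    s <- sum(as.double(adc[, j])) %% 65536
    if (s >= 32768) s <- s - 65536
    as.integer(s)
  }, integer(1L))
  hdr <- c(
    sprintf("%s %d %g %d", base, ncol(sig), record$sampling_rate, n),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
            base, gain, adc[1L, ], checksum, colnames(sig)))
  writeLines(hdr, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a WFDB record (.hea / .dat, format 16)
#'
#' Parses the header for the sampling rate, per-signal gain/baseline and
#' signal names, then decodes the interleaved 16-bit signal file.  Only
#' single-`.dat`, format-16 records (as written by [write_wfdb()]) are
#' supported.
#'
#' @param path record path, with or without the `.hea` extension.
#' @param lead_names leads to return, in the requested order
#'   (case-insensitive).  `NULL` returns all leads.
#' @return a `multi_lead_record` with amplitudes in the header's units
#'   (mV as written by this package).
#' @export
read_wfdb <- function(path, lead_names = NULL) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  dat <- paste0(path, ".dat")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) stop("malformed WFDB header: ", hea)
  nsig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  nsamp <- as.integer(top[4L])
  if (length(lines) < 1L + nsig) stop("header declares ", nsig,
                                      " signals but has too few lines")
  gains <- numeric(nsig); baselines <- numeric(nsig); names_ <- character(nsig)
  for (j in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[1L + j]), "\\s+")[[1L]]
    if (tok[2L] != "16")
      stop("unsupported WFDB signal format '", tok[2L], "' (only 16)")
    gspec <- sub("/.*$", "", tok[3L])  # e.g. "2000(0)" or "2000"
    base_l <- regmatches(gspec, regexec("\\(([-0-9]+)\\)", gspec))[[1L]]
    baselines[j] <- if (length(base_l) == 2L) as.numeric(base_l[2L]) else 0
    gains[j] <- as.numeric(sub("\\(.*$", "", gspec))
    if (!is.finite(gains[j]) || gains[j] == 0) gains[j] <- 200  # WFDB default
    names_[j] <- tok[length(tok)]
  }
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw_n <- file.size(dat) / 2L
  vals <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) != nsig * nsamp)
    stop("signal file length mismatch: expected ", nsig * nsamp,
         " samples, found ", length(vals))
  adc <- matrix(vals, ncol = nsig, byrow = TRUE)
  sig <- sweep(sweep(adc, 2L, baselines, "-"), 2L, gains, "/")
  colnames(sig) <- names_
  rec <- multi_lead_record(sig, fs, basename(path))
  if (is.null(lead_names)) rec else select_leads(rec, lead_names)
}

#' Write a record as delimited text
#'
#' One header line of lead names, one tab-separated row per sample, 12
#' significant digits (lossless round trip for typical mV-scale signals).
#' The sampling rate is stored in a `# sampling_rate:` comment line.
#'
#' @param record a `multi_lead_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %.12g", record$sampling_rate), con)
  writeLines(paste(colnames(record$signals), collapse = "\t"), con)
  body <- apply(format(record$signals, digits = 12L, trim = TRUE,
                       scientific = TRUE), 1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a delimited-text record
#'
#' The delimiter (tab or comma) is auto-detected from the header line.
#' A `# sampling_rate:` comment, if present, sets the record's sampling
#' rate; otherwise `default_rate` is used.
#'
#' @param path input file path.
#' @param default_rate sampling rate to assume when the file carries none.
#' @return a `multi_lead_record`.
#' @export
read_delimited <- function(path, default_rate = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fs <- default_rate
  m <- grep("^#\\s*sampling_rate:", lines)
  if (length(m)) fs <- as.numeric(sub("^#\\s*sampling_rate:\\s*", "", lines[m[1L]]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("empty or header-only signal file: ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], sep, fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != length(header)))
    stop("ragged rows: header has ", length(header), " columns but row(s) ",
         paste(utils::head(which(ncols != length(header))), collapse = ", "),
         " differ")
  sig <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = length(header), byrow = TRUE)
  if (anyNA(sig)) stop("non-numeric cell(s) in signal table: ", path)
  colnames(sig) <- header
  multi_lead_record(sig, fs, sub("\\.[^.]*$", "", basename(path)))
}
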