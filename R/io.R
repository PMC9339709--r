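# File interchange: BIDS-style events.tsv, classic EDF signal files, and
# JSON/YAML configuration helpers.

#' Write a BIDS-style events table
#'
#' Tab-separated, `n/a` for missing values, all columns (including unknown
#' extras) preserved verbatim.
#' @param events data.frame with at least `onset`, `duration`, `trial_type`.
#' @param path output path (conventionally `*_events.tsv`).
#' @export
write_events_tsv <- function(events, path) {
  df <- events
  for (cn in names(df)) {
    v <- df[[cn]]
    v <- as.character(v)
    v[is.na(v)] <- "n/a"
    df[[cn]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#' @param path path to an events.tsv.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  for (cn in names(df)) {
    v <- df[[cn]]
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num[!is.na(v)])) df[[cn]] <- num
  }
  df
}

# ---- classic EDF ------------------------------------------------------------
# Minimal EDF (16-bit) writer/reader: ASCII header blocks of 256 bytes plus
# little-endian int16 data records. Events are carried separately in
# events.tsv, as in a BIDS layout.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to a classic EDF file
#'
#' Signals are quantized to 16 bits over each channel's physical range, the
#' format's native resolution. Record duration is chosen so a whole number of
#' samples fits each record.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n_total <- ncol(rec$data)
  fs <- rec$sfreq
  assert_that(abs(fs - round(fs)) < 1e-9, "EDF writer needs an integer rate")
  spr <- as.integer(round(fs))                 # samples per 1 s record
  n_rec <- ceiling(n_total / spr)

  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("synthetic", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$ch_names, .edf_pad, "", width = 16),
    vapply(rec$ch_names, function(x) .edf_pad("AgAgCl", 80), ""),
    vapply(rec$ch_names, function(x) .edf_pad("uV", 8), ""),
    vapply(sprintf("%.6g", pmin_), .edf_pad, "", width = 8),
    vapply(sprintf("%.6g", pmax_), .edf_pad, "", width = 8),
    vapply(rec$ch_names, function(x) .edf_pad(dmin, 8), ""),
    vapply(rec$ch_names, function(x) .edf_pad(dmax, 8), ""),
    vapply(rec$ch_names, function(x) .edf_pad("", 80), ""),
    vapply(rec$ch_names, function(x) .edf_pad(spr, 8), ""),
    vapply(rec$ch_names, function(x) .edf_pad("", 32), ""))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1) * spr + 1
    idx <- i0:min(i0 + spr - 1, n_total)
    for (c_i in seq_len(ns)) {
      x <- rec$data[c_i, idx]
      if (length(idx) < spr) x <- c(x, rep(x[length(x)], spr - length(idx)))
      dig <- as.integer(pmin(pmax(round((x - pmin_[c_i]) * gain[c_i] + dmin),
                                  dmin), dmax))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a classic EDF file
#'
#' @param path path written by [write_edf()] (or any classic 16-bit EDF).
#' @param events optional events data.frame to attach.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  hdr <- rd(256)
  if (substr(hdr, 1, 1) != "0") stop_input("not a classic EDF file: %s", path)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1) stop_input("malformed EDF header (signal count)")

  get_fields <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  }
  labels <- get_fields(16)
  get_fields(80); get_fields(8)
  pmin_ <- as.numeric(get_fields(8))
  pmax_ <- as.numeric(get_fields(8))
  dmin <- as.numeric(get_fields(8))
  dmax <- as.numeric(get_fields(8))
  get_fields(80)
  spr <- as.integer(get_fields(8))
  get_fields(32)
  assert_that(length(unique(spr)) == 1, "mixed sampling rates unsupported")

  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (c_i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[c_i], size = 2, endian = "little")
      phys <- (dig - dmin[c_i]) * (pmax_[c_i] - pmin_[c_i]) /
        (dmax[c_i] - dmin[c_i]) + pmin_[c_i]
      data[c_i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
    }
  }
  eeg_recording(data, labels, fs, events)
}

#' Write a study configuration as YAML
#' @param config named list.
#' @param path output path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a study configuration (YAML)
#' @param path path to a YAML config.
#' @export
read_study_config <- function(path) yaml::read_yaml(path)

#' Write an object as JSON
#'
#' @param x object (list/data.frame).
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
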