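# Continuous EEG container, epoching, and basic signal conditioning.

#' Construct a continuous EEG recording
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param ch_names channel labels (unique; must match rows of `data`).
#' @param sfreq sampling rate in Hz.
#' @param events data.frame with at least `onset` (seconds) and `trial_type`;
#'   extra columns are carried along untouched.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, ch_names, sfreq, events = NULL) {
  data <- as.matrix(data)
  assert_that(is_scalar_num(sfreq) && sfreq > 0, "sfreq must be > 0")
  assert_that(nrow(data) == length(ch_names),
              "data must have one row per channel label")
  assert_that(!anyDuplicated(ch_names), "channel labels must be unique")
  if (is.null(events)) {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         trial_type = character(0))
  }
  assert_that(all(c("onset", "trial_type") %in% names(events)),
              "events need `onset` and `trial_type` columns")
  structure(list(data = data, ch_names = as.character(ch_names),
                 sfreq = sfreq, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) n_samples(rec) / rec$sfreq

channel_index <- function(rec, channel) {
  idx <- match(channel, rec$ch_names)
  if (is.na(idx)) stop_input("channel '%s' not present in recording", channel)
  idx
}

#' Extract fixed-length epochs around events
#'
#' Windows are half-open `[tmin, tmax)` in seconds relative to each event
#' onset; an epoch therefore spans `round((tmax - tmin) * sfreq)` samples.
#' Events whose window exceeds the recording are dropped with a log entry.
#'
#' @param rec an [eeg_recording()].
#' @param window numeric length-2, `c(tmin, tmax)` seconds relative to onset.
#' @param baseline optional `c(bmin, bmax)`: per-epoch, per-channel mean over
#'   this window is subtracted.
#' @param events optional subset of `rec$events` rows to epoch (data.frame);
#'   defaults to all events.
#' @return object of class `epoch_set`: list with `data` (trials x channels x
#'   samples), `times`, `ch_names`, `sfreq`, `events`, `window`, `baseline`,
#'   `kept`, `rejected`, `rejection_log`.
#' @export
epoch_recording <- function(rec, window, baseline = NULL, events = NULL) {
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be c(tmin, tmax) with tmin < tmax")
  events <- events %||% rec$events
  fs <- rec$sfreq
  rel <- seq.int(round(window[1] * fs), round(window[2] * fs) - 1L)
  times <- rel / fs

  onset_smp <- time_to_sample(events$onset, fs)
  ok <- (onset_smp + rel[1]) >= 1 & (onset_smp + rel[length(rel)]) <= n_samples(rec)
  if (!any(ok)) stop_input("no event window fits inside the recording")
  events <- events[ok, , drop = FALSE]
  onset_smp <- onset_smp[ok]

  nt <- length(onset_smp); nc <- nrow(rec$data); ns <- length(rel)
  arr <- array(NA_real_, dim = c(nt, nc, ns))
  for (i in seq_len(nt)) {
    arr[i, , ] <- rec$data[, onset_smp[i] + rel, drop = FALSE]
  }

  ep <- structure(list(data = arr, times = times, ch_names = rec$ch_names,
                       sfreq = fs, events = events, window = window,
                       baseline = baseline, kept = seq_len(nt),
                       rejected = integer(0),
                       rejection_log = data.frame(trial = integer(0),
                                                  reason = character(0))),
                  class = "epoch_set")
  if (!is.null(baseline)) ep <- baseline_correct(ep, baseline)
  ep
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%g, %g) s; %d kept / %d rejected\n",
              d[1], d[2], d[3], x$sfreq, x$window[1], x$window[2],
              length(x$kept), length(x$rejected)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over the half-open baseline
#' window from the whole epoch.
#'
#' @param ep an `epoch_set`.
#' @param baseline `c(bmin, bmax)` seconds.
#' @export
baseline_correct <- function(ep, baseline) {
  sel <- ep$times >= baseline[1] & ep$times < baseline[2]
  assert_that(any(sel), "baseline window does not overlap the epoch")
  bl <- rowMeans(ep$data[, , sel, drop = FALSE], dims = 2)
  ep$data <- ep$data - array(bl, dim = dim(ep$data))
  ep$baseline <- baseline
  ep
}

# Drop epochs (bookkeeping for the rejection stages).
drop_epochs <- function(ep, idx, reason) {
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(ep)
  keep <- setdiff(seq_len(n_trials(ep)), idx)
  if (!length(keep)) stop_input("all epochs rejected (%s): block unusable", reason)
  orig_kept <- ep$kept
  ep$rejection_log <- rbind(ep$rejection_log,
                            data.frame(trial = orig_kept[idx],
                                       reason = rep(reason, length(idx))))
  ep$rejected <- c(ep$rejected, orig_kept[idx])
  ep$kept <- orig_kept[keep]
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$events <- ep$events[keep, , drop = FALSE]
  ep
}

# ---- continuous-signal conditioning ----------------------------------------

apply_by_channel <- function(rec, fun) {
  for (i in seq_len(nrow(rec$data))) rec$data[i, ] <- fun(rec$data[i, ])
  rec
}

#' Remove per-channel linear trends
#' @param rec an [eeg_recording()].
#' @export
detrend_recording <- function(rec) {
  n <- n_samples(rec)
  t <- seq_len(n) - (n + 1) / 2           # centered regressor
  stt <- sum(t * t)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    b <- sum(t * x) / stt
    rec$data[i, ] <- x - mean(x) - b * t
  }
  rec
}

# Zero-phase band limiting in the frequency domain: the signal is extended by
# its mirror image (even periodic extension, so there is no wrap-around
# discontinuity), multiplied by the squared-magnitude Butterworth response
# (the same magnitude a forward-backward IIR pass realizes, with exactly zero
# phase), and transformed back. O(n log n) per channel and stable at
# arbitrarily low cutoffs.
fft_filter <- function(x, fs, highpass = NULL, lowpass = NULL,
                       hp_order = 2, lp_order = 8) {
  n <- length(x)
  # pad to a 5-smooth length (mixed-radix FFTs are pathological on lengths
  # with large prime factors) by recycling the even periodic extension; the
  # single wrap discontinuity then sits >= n samples away from the retained
  # segment, far beyond any filter's impulse support
  np <- stats::nextn(2L * n, c(2L, 3L, 5L))
  xp <- rep_len(c(x, rev(x)), np)
  f <- (0:(np - 1)) * fs / np
  f <- pmin(f, fs - f)                   # two-sided |frequency|
  H <- rep(1, np)
  if (!is.null(lowpass)) H <- H / (1 + (f / lowpass)^(2 * lp_order))
  if (!is.null(highpass)) {
    Hhp <- 1 / (1 + (highpass / pmax(f, .Machine$double.eps))^(2 * hp_order))
    Hhp[f == 0] <- 0
    H <- H * Hhp
  }
  Re(stats::fft(stats::fft(xp) * H, inverse = TRUE) / np)[seq_len(n)]
}

# Matrix version: rows are channels; two real channels share one complex FFT
# (the response is real, so real and imaginary parts filter independently).
.filter_cache <- new.env(parent = emptyenv())

fft_filter_matrix <- function(data, fs, highpass = NULL, lowpass = NULL,
                              hp_order = 2, lp_order = 8) {
  nch <- nrow(data); n <- ncol(data)
  np <- stats::nextn(2L * n, c(2L, 3L, 5L))
  key <- paste(np, fs, highpass %||% "-", lowpass %||% "-", hp_order, lp_order)
  H <- .filter_cache[[key]]
  if (is.null(H)) {
    f <- (0:(np - 1)) * fs / np
    f <- pmin(f, fs - f)
    H <- rep(1, np)
    if (!is.null(lowpass)) H <- H / (1 + (f / lowpass)^(2 * lp_order))
    if (!is.null(highpass)) {
      Hhp <- 1 / (1 + (highpass / pmax(f, .Machine$double.eps))^(2 * hp_order))
      Hhp[f == 0] <- 0
      H <- H * Hhp
    }
    if (length(ls(.filter_cache)) > 30) rm(list = ls(.filter_cache),
                                           envir = .filter_cache)
    .filter_cache[[key]] <- H
  }
  for (i in seq(1, nch, by = 2)) {
    z <- if (i + 1 <= nch) data[i, ] + 1i * data[i + 1, ] else data[i, ] + 0i
    zp <- rep_len(c(z, rev(z)), np)
    zf <- stats::fft(stats::fft(zp) * H, inverse = TRUE)[seq_len(n)] / np
    data[i, ] <- Re(zf)
    if (i + 1 <= nch) data[i + 1, ] <- Im(zf)
  }
  data
}

#' Band-limit a recording with zero-phase Butterworth-magnitude filters
#'
#' @param rec an [eeg_recording()].
#' @param highpass high-pass cutoff in Hz, or `NULL` to skip.
#' @param lowpass low-pass cutoff in Hz, or `NULL` to skip.
#' @param hp_order,lp_order effective two-pass filter orders.
#' @export
filter_recording <- function(rec, highpass = NULL, lowpass = NULL,
                             hp_order = 2, lp_order = 8) {
  nyq <- rec$sfreq / 2
  if (!is.null(lowpass)) {
    assert_that(lowpass < nyq, "lowpass must be below the Nyquist frequency")
  }
  if (!is.null(highpass)) {
    assert_that(highpass > 0 && highpass < nyq, "highpass must lie in (0, Nyquist)")
  }
  rec$data <- fft_filter_matrix(rec$data, rec$sfreq, highpass, lowpass,
                                hp_order, lp_order)
  rec
}

#' Integer-factor downsampling with anti-alias filtering
#'
#' @param rec an [eeg_recording()].
#' @param target_rate new sampling rate; `sfreq / target_rate` must be an
#'   integer. Event onsets are in seconds and carry over unchanged.
#' @export
resample_recording <- function(rec, target_rate) {
  if (abs(rec$sfreq - target_rate) < 1e-9) return(rec)
  q <- rec$sfreq / target_rate
  assert_that(abs(q - round(q)) < 1e-9 && q >= 1,
              "sfreq must be an integer multiple of target_rate")
  q <- as.integer(round(q))
  new <- t(apply(rec$data, 1, function(x) signal::decimate(x, q)))
  rec$data <- new
  rec$sfreq <- target_rate
  rec
}

#' Re-reference to the common average
#' @param rec an [eeg_recording()].
#' @export
rereference_car <- function(rec) {
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Concatenate two recordings in time
#'
#' Used to merge the pre- and post-intervention blocks before offline
#' preprocessing; the second recording's events are shifted by the duration of
#' the first and tagged via a `block` column if present.
#' @param a,b [eeg_recording()]s with identical channels and rates.
#' @export
concat_recordings <- function(a, b) {
  assert_that(identical(a$ch_names, b$ch_names), "channel sets differ")
  assert_that(abs(a$sfreq - b$sfreq) < 1e-9, "sampling rates differ")
  offset <- rec_duration(a)
  eb <- b$events
  eb$onset <- eb$onset + offset
  cols <- union(names(a$events), names(eb))
  for (cn in setdiff(cols, names(a$events))) a$events[[cn]] <- NA
  for (cn in setdiff(cols, names(eb))) eb[[cn]] <- NA
  eeg_recording(cbind(a$data, b$data), a$ch_names, a$sfreq,
                rbind(a$events[cols], eb[cols]))
}
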