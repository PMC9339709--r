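# Offline ERP pipeline: merge pre/post blocks, clean, epoch, trial-by-trial
# rejection with interpolation, average, and window measures.

#' Offline ERP configuration
#'
#' Defaults follow the offline protocol: merge pre/post, resample to 250 Hz,
#' 0.5-40 Hz band, common-average reference, 6 Hz low-pass on the ERP branch
#' only (to exclude alpha), epochs -0.5..1.5 s with -0.5..0 baseline,
#' trial-by-trial rejection at 150 uV peak-to-peak / 15% bad-epoch fraction /
#' >10 bad channels, P300 mean window 200-550 ms (the 250-550 ms variant used
#' in some figures is available via `p300_mean_window`), max window
#' 250-550 ms, late window 700-1000 ms, measured at Pz.
#'
#' @param resample_rate Hz.
#' @param bandpass `c(high, low)` edges in Hz.
#' @param erp_lowpass ERP-branch low-pass in Hz.
#' @param epoch_window,baseline seconds.
#' @param amp_threshold per-channel peak-to-peak limit in microvolts.
#' @param max_bad_epoch_fraction channel exclusion threshold (fraction).
#' @param max_bad_channels per-epoch bad-channel limit (epoch dropped above).
#' @param p300_mean_window,p300_max_window,late_window ms.
#' @param measure_channel channel for the reported amplitudes.
#' @export
offline_config <- function(resample_rate = 250, bandpass = c(0.5, 40),
                           erp_lowpass = 6, epoch_window = c(-0.5, 1.5),
                           baseline = c(-0.5, 0), amp_threshold = 150,
                           max_bad_epoch_fraction = 0.15,
                           max_bad_channels = 10,
                           p300_mean_window = c(200, 550),
                           p300_max_window = c(250, 550),
                           late_window = c(700, 1000),
                           measure_channel = "Pz") {
  assert_that(amp_threshold > 0 && max_bad_epoch_fraction > 0,
              "thresholds must be positive")
  structure(as.list(environment()), class = "offline_config")
}

#' Merge and clean the pre/post blocks
#'
#' Concatenates the two blocks (tagging events with a `block` column),
#' resamples both to `cfg$resample_rate` (reconciling 500 and 250 Hz
#' recordings), band-filters, detrends, optionally excises marked artifact
#' segments, and repairs named bad channels by spherical-spline
#' interpolation. More than 3 bad channels triggers a warning (the protocol
#' repaired at most 3) but proceeds.
#'
#' @param raw_pre,raw_post [eeg_recording()]s of the two blocks.
#' @param cfg an [offline_config()].
#' @param bad_channels labels to interpolate.
#' @param exclude_segments optional data.frame `start`,`end` (seconds, in the
#'   merged time base) zeroed out as artifactual; events inside are dropped.
#' @export
preprocess_offline <- function(raw_pre, raw_post, cfg = offline_config(),
                               bad_channels = character(0),
                               exclude_segments = NULL) {
  raw_pre$events$block <- rep("pre", nrow(raw_pre$events))
  raw_post$events$block <- rep("post", nrow(raw_post$events))
  raw_pre <- resample_recording(raw_pre, cfg$resample_rate)
  raw_post <- resample_recording(raw_post, cfg$resample_rate)
  merged <- concat_recordings(raw_pre, raw_post)
  merged <- filter_recording(merged, highpass = cfg$bandpass[1],
                             lowpass = cfg$bandpass[2])
  merged <- detrend_recording(merged)

  if (!is.null(exclude_segments)) {
    for (i in seq_len(nrow(exclude_segments))) {
      i0 <- time_to_sample(exclude_segments$start[i], merged$sfreq)
      i1 <- time_to_sample(exclude_segments$end[i], merged$sfreq)
      merged$data[, i0:i1] <- 0
      inside <- merged$events$onset >= exclude_segments$start[i] &
        merged$events$onset <= exclude_segments$end[i]
      merged$events <- merged$events[!inside, , drop = FALSE]
    }
  }

  if (length(bad_channels)) {
    if (length(bad_channels) > 3) {
      warning(sprintf("interpolating %d channels; protocol repaired at most 3",
                      length(bad_channels)))
    }
    merged$data <- spline_interpolate(merged$data, merged$ch_names,
                                      bad_channels)
  }
  merged
}

#' Trial-by-trial rejection with channel interpolation
#'
#' Three passes, with the protocol's strict inequalities: (1) per epoch, mark
#' channels whose within-epoch peak-to-peak amplitude exceeds
#' `cfg$amp_threshold` (strictly); (2) channels marked in strictly more than
#' `cfg$max_bad_epoch_fraction` of epochs are excluded everywhere; (3) epochs
#' with strictly more than `cfg$max_bad_channels` marked channels are
#' dropped, and in retained epochs the marked channels (plus globally
#' excluded ones) are replaced by spherical-spline interpolation. Retained
#' epochs' unmarked channels are never altered.
#'
#' @param epochs an `epoch_set`.
#' @param cfg an [offline_config()].
#' @return the cleaned `epoch_set`; attribute `excluded_channels` lists
#'   globally excluded labels.
#' @export
tbt_reject <- function(epochs, cfg = offline_config()) {
  nt <- n_trials(epochs); nc <- dim(epochs$data)[2]
  # peak-to-peak per (trial, channel); loop over whichever dimension is short
  ns <- dim(epochs$data)[3]
  flat <- matrix(epochs$data, nt * nc, ns)
  if (nt * nc <= ns) {
    ptp <- matrix(vapply(seq_len(nt * nc), function(r) {
      x <- flat[r, ]
      max(x) - min(x)
    }, 0), nt, nc)
  } else {
    hi <- flat[, 1]; lo <- flat[, 1]
    for (s in seq_len(ns)[-1]) {
      hi <- pmax(hi, flat[, s]); lo <- pmin(lo, flat[, s])
    }
    ptp <- matrix(hi - lo, nt, nc)
  }
  marked <- ptp > cfg$amp_threshold                       # strict: > 150 uV

  bad_frac <- colMeans(marked)
  excl_ch <- which(bad_frac > cfg$max_bad_epoch_fraction) # strict: > 15%
  marked[, excl_ch] <- TRUE

  n_bad <- rowSums(marked)
  drop_idx <- which(n_bad > cfg$max_bad_channels)         # strict: > 10
  if (length(drop_idx) == nt) stop_input("trial-by-trial rejection dropped every epoch")
  if (length(drop_idx)) {
    epochs <- drop_epochs(epochs, drop_idx, "tbt_bad_channels")
    marked <- marked[-drop_idx, , drop = FALSE]
  }

  for (i in seq_len(nrow(marked))) {
    bad <- which(marked[i, ])
    if (length(bad)) {
      epochs$data[i, , ] <- spline_interpolate(
        epochs$data[i, , , drop = TRUE], epochs$ch_names, bad)
    }
  }
  attr(epochs, "excluded_channels") <- epochs$ch_names[excl_ch]
  epochs
}

# Window measures on an average waveform: mean over the half-open window and
# max with its latency (earliest sample on ties).
measure_window <- function(avg, times, window_ms) {
  sel <- which(times >= window_ms[1] / 1000 & times < window_ms[2] / 1000)
  assert_that(length(sel) > 0, "measurement window outside the epoch")
  seg <- avg[sel]
  i_max <- sel[which.max(seg)]
  list(mean = mean(seg), max = max(seg), max_latency_ms = times[i_max] * 1000)
}

#' Average epochs and measure ERP windows
#'
#' Baseline-corrected across-epoch average with the three protocol measures
#' at the configured channel: P300 mean amplitude (200-550 ms), P300 maximum
#' peak with latency (250-550 ms), and the late-ERP mean (700-1000 ms).
#'
#' @param epochs an `epoch_set` (>= 1 retained epoch).
#' @param cfg an [offline_config()].
#' @return `erp_result`: list with `average` (channels x samples), `times`,
#'   `ch_names`, `n_epochs`, `p300_mean`, `p300_max`, `p300_max_latency_ms`,
#'   `late_mean`.
#' @export
compute_erp <- function(epochs, cfg = offline_config()) {
  assert_that(n_trials(epochs) >= 1, "no retained epochs")
  avg <- colMeans(epochs$data)           # over trials: channels x samples
  c_i <- match(cfg$measure_channel, epochs$ch_names)
  if (is.na(c_i)) stop_input("channel '%s' not present", cfg$measure_channel)
  ch <- avg[c_i, ]
  m_mean <- measure_window(ch, epochs$times, cfg$p300_mean_window)
  m_max <- measure_window(ch, epochs$times, cfg$p300_max_window)
  m_late <- measure_window(ch, epochs$times, cfg$late_window)
  structure(list(average = avg, times = epochs$times,
                 ch_names = epochs$ch_names, n_epochs = n_trials(epochs),
                 p300_mean = m_mean$mean, p300_max = m_max$max,
                 p300_max_latency_ms = m_max$max_latency_ms,
                 late_mean = m_late$mean),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> n=%d epochs; P300 mean %.2f uV, max %.2f uV @ %.0f ms, late %.2f uV\n",
              x$n_epochs, x$p300_mean, x$p300_max, x$p300_max_latency_ms,
              x$late_mean))
  invisible(x)
}

#' Mean amplitude of the late ERP window
#'
#' Exploratory late-component measure: same averaging and channel as the P300
#' but with the window shifted to 700-1000 ms.
#' @param erp an `erp_result`.
#' @param cfg an [offline_config()].
#' @export
measure_late_erp <- function(erp, cfg = offline_config()) {
  c_i <- match(cfg$measure_channel, erp$ch_names)
  measure_window(erp$average[c_i, ], erp$times, cfg$late_window)$mean
}

#' Run the ERP branch for one session (merged recording -> condition ERPs)
#'
#' Applies the ERP-only conditioning (common-average reference, 6 Hz
#' low-pass), epochs the merged recording, splits pre/post x target/standard,
#' baseline-corrects, runs trial-by-trial rejection per subset, and averages.
#'
#' @param merged output of [preprocess_offline()].
#' @param cfg an [offline_config()].
#' @param trial_types conditions to extract (default target + standard).
#' @return nested list `result[[block]][[trial_type]]` of `erp_result`s
#'   (missing conditions reported as `NULL`).
#' @export
erp_by_condition <- function(merged, cfg = offline_config(),
                             trial_types = c("target", "standard")) {
  branch <- rereference_car(merged)
  branch <- filter_recording(branch, lowpass = cfg$erp_lowpass, lp_order = 4)
  out <- list()
  for (bl in unique(merged$events$block)) {
    out[[bl]] <- list()
    for (tt in trial_types) {
      ev <- branch$events[branch$events$block == bl &
                          branch$events$trial_type == tt, , drop = FALSE]
      if (!nrow(ev)) { out[[bl]][[tt]] <- NULL; next }
      ep <- epoch_recording(branch, cfg$epoch_window, baseline = cfg$baseline,
                            events = ev)
      ep <- tbt_reject(ep, cfg)
      out[[bl]][[tt]] <- compute_erp(ep, cfg)
    }
  }
  out
}
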