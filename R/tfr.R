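# Morlet continuous wavelet decomposition of target epochs and ROI power.

#' Time-frequency configuration
#'
#' 47 log-spaced frequencies from 0.25 to 6 Hz over -0.5..+1.6 s epochs;
#' region of interest 0.5-5.5 Hz x 250-550 ms at Pz. The analyzing wavelet is
#' an analytic Morlet with a constant quality factor (`n_cycles` cycles at
#' every frequency), so its relative bandwidth matches the logarithmic
#' frequency grid; the long time support this implies at the lowest
#' frequencies is flagged by the cone-of-influence mask rather than truncated.
#'
#' @param epoch_window seconds relative to target onset.
#' @param baseline seconds (time-domain subtraction before the CWT).
#' @param freq_range `c(min, max)` Hz.
#' @param n_freqs number of log-spaced frequencies (>= 2).
#' @param n_cycles wavelet cycles (constant across frequency).
#' @param roi_time ms, `c(250, 550)`.
#' @param roi_freq Hz, `c(0.5, 5.5)`.
#' @param channel analysis channel.
#' @export
tfr_config <- function(epoch_window = c(-0.5, 1.6), baseline = c(-0.5, 0),
                       freq_range = c(0.25, 6), n_freqs = 47, n_cycles = 10,
                       roi_time = c(250, 550), roi_freq = c(0.5, 5.5),
                       channel = "Pz") {
  assert_that(n_freqs >= 2, "n_freqs must be >= 2")
  assert_that(freq_range[1] > 0 && freq_range[1] < freq_range[2],
              "freq_range must be increasing and positive")
  structure(as.list(environment()), class = "tfr_config")
}

#' Log-spaced frequency axis
#' @param cfg a [tfr_config()].
#' @export
tfr_freqs <- function(cfg = tfr_config()) {
  exp(seq(log(cfg$freq_range[1]), log(cfg$freq_range[2]),
          length.out = cfg$n_freqs))
}

# Analytic Morlet transform of a single trace via FFT convolution.
# Wavelets are L2-normalized so white noise yields a flat expected power
# profile across frequencies.
morlet_cwt <- function(x, fs, freqs, n_cycles) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  fgrid <- (0:(nfft - 1)) * fs / nfft
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f0)
    sigma_f <- 1 / (2 * pi * sigma_t)
    # frequency response of the analytic, L2-normalized Morlet
    H <- exp(-((fgrid - f0)^2) / (2 * sigma_f^2))
    H[fgrid > fs / 2] <- 0                       # analytic: kill negatives
    norm <- sqrt(sum(Mod(H)^2) / nfft)           # unit discrete L2 norm
    W <- stats::fft(X * H / norm, inverse = TRUE) / nfft
    out[k, ] <- W[seq_len(n)]
  }
  out
}

#' Continuous wavelet transform of target epochs
#'
#' Per retained epoch, analytic-Morlet power at the analysis channel is
#' computed, log10-transformed, and then averaged across epochs (log first,
#' then average - the order matters and is fixed). An edge-validity mask
#' marks time-frequency cells within two wavelet standard deviations of the
#' epoch edges (cone of influence).
#'
#' @param epochs an `epoch_set`.
#' @param cfg a [tfr_config()].
#' @return `tfr_result`: list `log_power` (freqs x times), `freqs`, `times`,
#'   `edge_mask` (TRUE = edge-contaminated), `n_epochs`.
#' @export
compute_cwt <- function(epochs, cfg = tfr_config()) {
  c_i <- match(cfg$channel, epochs$ch_names)
  if (is.na(c_i)) stop_input("channel '%s' not present", cfg$channel)
  freqs <- tfr_freqs(cfg)
  nt <- n_trials(epochs)
  times <- epochs$times
  acc <- matrix(0, length(freqs), length(times))
  for (i in seq_len(nt)) {
    W <- morlet_cwt(epochs$data[i, c_i, ], epochs$sfreq, freqs, cfg$n_cycles)
    acc <- acc + log10(pmax(Mod(W)^2, .Machine$double.xmin))
  }
  log_power <- acc / nt

  sigma_t <- cfg$n_cycles / (2 * pi * freqs)
  edge <- outer(sigma_t, times, function(s, t) {
    t < (times[1] + 2 * s) | t > (times[length(times)] - 2 * s)
  })
  structure(list(log_power = log_power, freqs = freqs, times = times,
                 edge_mask = edge, n_epochs = nt),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  cat(sprintf("<tfr_result> %d freqs (%.2f-%.2f Hz) x %d times, %d epochs\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$n_epochs))
  invisible(x)
}

#' Mean log-power over the delta/theta region of interest
#'
#' Arithmetic mean of the averaged log10 power over all cells in
#' `roi_freq x roi_time`. Edge-masked cells are included (the ROI overlaps
#' the cone of influence at its lowest frequencies by design) but an
#' edge-excluded variant is reported alongside.
#'
#' @param tfr a `tfr_result`.
#' @param cfg a [tfr_config()].
#' @return list `roi_mean`, `roi_mean_edge_excluded`, `n_bins`, `n_masked`.
#' @export
roi_power <- function(tfr, cfg = tfr_config()) {
  fsel <- tfr$freqs >= cfg$roi_freq[1] & tfr$freqs <= cfg$roi_freq[2]
  tsel <- tfr$times >= cfg$roi_time[1] / 1000 &
    tfr$times <= cfg$roi_time[2] / 1000
  assert_that(any(fsel) && any(tsel), "empty region of interest")
  block <- tfr$log_power[fsel, tsel, drop = FALSE]
  mask <- tfr$edge_mask[fsel, tsel, drop = FALSE]
  valid <- block[!mask]
  list(roi_mean = mean(block),
       roi_mean_edge_excluded = if (length(valid)) mean(valid) else NA_real_,
       n_bins = length(block), n_masked = sum(mask))
}

#' Run the TFR branch for one session
#'
#' Re-references the merged recording to the common average, epochs the
#' target trials (-0.5..1.6 s, -0.5..0 baseline), applies trial-by-trial
#' rejection, and returns per-block wavelet results with their ROI means.
#'
#' @param merged output of [preprocess_offline()].
#' @param cfg a [tfr_config()].
#' @param erp_cfg the [offline_config()] used for epoch rejection.
#' @return list `result[[block]]` with `tfr` and `roi`.
#' @export
tfr_by_condition <- function(merged, cfg = tfr_config(),
                             erp_cfg = offline_config()) {
  branch <- rereference_car(merged)
  out <- list()
  for (bl in unique(merged$events$block)) {
    ev <- branch$events[branch$events$block == bl &
                        branch$events$trial_type == "target", , drop = FALSE]
    if (!nrow(ev)) { out[[bl]] <- NULL; next }
    ep <- epoch_recording(branch, cfg$epoch_window, baseline = cfg$baseline,
                          events = ev)
    ep <- tbt_reject(ep, erp_cfg)
    tf <- compute_cwt(ep, cfg)
    out[[bl]] <- list(tfr = tf, roi = roi_power(tf, cfg))
  }
  out
}
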