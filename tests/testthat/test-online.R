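# Online stage: filtering, component removal, statistical epoch rejection,
# and the individual parameter estimates.

test_that("online preprocessing band-limits and detrends", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  mk <- function(x) eeg_recording(matrix(x, 1), "Pz", fs)
  inner <- 1000:4000

  out50 <- preprocess_online(mk(sin(2 * pi * 50 * t)))
  expect_lt(max(abs(out50$data[1, inner])), 0.05)          # stopband

  drift <- preprocess_online(mk(2 + 0.5 * t))
  expect_lt(max(abs(drift$data[1, inner])), 0.05)          # DC + trend

  pass <- preprocess_online(mk(sin(2 * pi * 3 * t)))
  expect_equal(max(abs(pass$data[1, inner])), 1, tolerance = 0.05)  # passband

  expect_error(preprocess_online(mk(t), online_config(lowpass = 400)),
               "Nyquist")
})

test_that("component removal honors its contract (identity, oracle, idempotence)", {
  set.seed(8)
  n <- 2000
  labels <- c("Fp1", "Fp2", "Cz", "Pz")
  clean <- matrix(rnorm(4 * n, sd = 1), 4, n)
  blink <- exp(-((seq_len(n) - 1000) / 40)^2) * 60
  mix_w <- c(1, 0.8, 0.2, 0.05)                 # frontal blink topography
  raw <- eeg_recording(clean + outer(mix_w, blink), labels, 250)

  A <- cbind(mix_w, c(0, 0, 1, 0))
  U <- solve(crossprod(A), t(A))             # pseudo-inverse: U %*% A = I
  dec <- list(mixing = A, unmixing = U)

  none <- remove_artifact_components(raw, dec, integer(0))
  expect_equal(none$data, raw$data)

  fixed <- remove_artifact_components(raw, dec, select_by_reference(blink, 0.7))
  v_before <- stats::var(raw$data[1, ])
  v_after <- stats::var(fixed$data[1, ])
  resid_var <- stats::var(clean[1, ])
  expect_lt((v_after - resid_var) / (v_before - resid_var), 0.1)

  # removal is a projection: applying it twice changes nothing
  twice <- remove_artifact_components(fixed, dec, 1L)
  expect_equal(twice$data, fixed$data, tolerance = 1e-8)

  expect_error(remove_artifact_components(raw, dec, 1:2), "every component")
})

test_that("statistical rejection flags only outlier epochs", {
  set.seed(2)
  arr <- array(rnorm(100 * 3 * 200), c(100, 3, 200))
  ep <- make_epochs(arr)

  spiky <- arr
  spiky[7, 2, 90:110] <- spiky[7, 2, 90:110] + 500
  eps <- make_epochs(spiky)
  out <- reject_epochs_stat(eps, 3)
  expect_true(7 %in% out$rejected)
  expect_true(nrow(out$rejection_log) >= 1)
  # retained epochs' samples are untouched
  kept1 <- out$kept[1]
  expect_identical(out$data[1, , ], spiky[kept1, , ])

  # identical epochs: zero variance across epochs, nothing to reject
  same <- make_epochs(array(rep(sin(seq_len(200) / 10), each = 300),
                            c(100, 3, 200)))
  expect_equal(p300tacs:::n_trials(reject_epochs_stat(same, 3)), 100)

  # infinite threshold rejects nothing
  expect_equal(p300tacs:::n_trials(reject_epochs_stat(eps, Inf)), 100)

  expect_error(reject_epochs_stat(make_epochs(arr[1:2, , , drop = FALSE]), 3),
               "at least 3")
})

test_that("latency estimation is exact noiseless and tie-breaks early", {
  fs <- 500
  times <- seq(-2, 5 - 1 / fs, by = 1 / fs)
  tr <- burst_trace(times, 0.35, 4)
  ep <- make_epochs(array(rep(tr, each = 3), c(3, 1, length(times))),
                    sfreq = fs, tmin = -2, ch_names = "Pz")
  est <- estimate_p300_latency(ep)
  expect_equal(est$latency_ms, 350)
  expect_false(est$low_confidence)

  flat <- make_epochs(array(0, c(3, 1, length(times))), sfreq = fs,
                      tmin = -2, ch_names = "Pz")
  est0 <- estimate_p300_latency(flat)
  expect_equal(est0$latency_ms, 250)          # earliest window sample
  expect_true(est0$low_confidence)

  expect_error(estimate_p300_latency(ep, channel = "Cz"), "not present")
})

test_that("frequency estimation is within a bin noiseless and tie-breaks low", {
  fs <- 500
  times <- seq(-2, 5 - 1 / fs, by = 1 / fs)
  ep <- make_epochs(array(burst_trace(times, 0.35, 3), c(1, 1, length(times))),
                    sfreq = fs, tmin = -2, ch_names = "Pz")
  # matched-template: within one grid bin
  est_m <- estimate_stim_frequency(ep, 350, method = "matched")
  expect_lt(abs(est_m$stim_frequency - 3), 0.11)
  # raw spectral argmax: within the burst's own peak flatness (the ~1.3-cycle
  # burst has sigma_f ~ 0.64 f, so its periodogram top is shallow and the
  # negative-frequency mirror biases the argmax by a fraction of a hertz)
  est_e <- estimate_stim_frequency(ep, 350, method = "evoked")
  expect_lt(abs(est_e$stim_frequency - 3), 0.3)

  # exact spectral ties resolve to the lower frequency (flat zero spectrum:
  # every bin ties, the band's lower edge is returned)
  flat <- make_epochs(array(0, c(1, 1, length(times))), sfreq = fs,
                      tmin = -2, ch_names = "Pz")
  expect_equal(estimate_stim_frequency(flat, 350,
                                       method = "matched")$stim_frequency, 1)
  # the periodogram backend ties resolve to its lowest in-band grid point
  expect_lte(estimate_stim_frequency(flat, 350,
                                     method = "evoked")$stim_frequency, 1.05)

  expect_error(estimate_stim_frequency(ep, 4900), "outside the epoch")
})

test_that("noisy single-subject recovery lands near the configured truth", {
  sq <- generate_sequence(400, 0.25, seed = 21)
  truth <- erp_ground_truth(p300_latency = 420, ero_frequency = 4.6)
  rec <- simulate_recording(recording_spec(sampling_rate = 250), sq, truth,
                            noise_spec(), seed = 22)
  par <- estimate_stim_params(rec)
  expect_lt(abs(par$p300_latency_ms - 420), 16)
  expect_lt(abs(par$stim_frequency_hz - 4.6), 0.6)
  expect_gt(par$n_epochs_used, 50)
})
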