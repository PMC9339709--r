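# Synthetic EEG / behavior generator: construction guarantees, determinism,
# and statistical structure.

test_that("noiseless recording places the P300 peak exactly as configured", {
  sq1 <- data.frame(onset = 1.0, trial_type = "target", tilt = "right")
  truth <- erp_ground_truth(p300_latency = 350, p300_amplitude = 5,
                            n700_amplitude = 0)
  rec <- simulate_recording(recording_spec(duration = 4), sq1, truth,
                            silent_noise(), seed = 1)
  pz <- rec$data[match("Pz", rec$ch_names), ]
  i <- which.max(pz)
  t_peak <- (i - 1) / rec$sfreq - 1.0
  expect_equal(t_peak, 0.350)
  expect_equal(pz[i], 5)
  expect_gte(t_peak, 0.250)
  expect_lte(t_peak, 0.450)
})

test_that("marker stream carries the full oddball design", {
  sq <- generate_sequence(400, 0.25, seed = 1)
  rec <- simulate_recording(recording_spec(sampling_rate = 250), sq,
                            erp_ground_truth(), silent_noise(), seed = 1)
  expect_equal(nrow(rec$events), 400)
  expect_equal(sum(rec$events$trial_type == "target"), 100)
})

test_that("identical seeds give identical recordings, different seeds differ", {
  sq <- generate_sequence(20, 0.25, seed = 3)
  spec <- recording_spec(sampling_rate = 250)
  a <- simulate_recording(spec, sq, erp_ground_truth(), noise_spec(), seed = 9)
  b <- simulate_recording(spec, sq, erp_ground_truth(), noise_spec(), seed = 9)
  c <- simulate_recording(spec, sq, erp_ground_truth(), noise_spec(), seed = 10)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("generator rejects invalid inputs", {
  sq <- data.frame(onset = 100, trial_type = "target", tilt = "left")
  expect_error(simulate_recording(recording_spec(duration = 5), sq,
                                  erp_ground_truth(), silent_noise(), 1),
               "duration")
  expect_error(recording_spec(channel_labels = c("Pz", "NotAChannel")),
               "unknown channel")
  expect_error(recording_spec(channel_labels = c("Cz", "Fz")), "Pz")
  expect_error(erp_ground_truth(ero_frequency = 12), "1, 8")
})

test_that("target/standard amplitude ratio and topography shape the ERP", {
  sq <- data.frame(onset = c(1, 4), trial_type = c("target", "standard"),
                   tilt = c("right", "left"))
  truth <- erp_ground_truth(n700_amplitude = 0, target_standard_ratio = 3)
  rec <- simulate_recording(recording_spec(duration = 8), sq, truth,
                            silent_noise(), seed = 1)
  pz <- match("Pz", rec$ch_names)
  fp1 <- match("Fp1", rec$ch_names)
  t_peak <- function(on) p300tacs:::time_to_sample(on + 0.35, rec$sfreq)
  expect_equal(rec$data[pz, t_peak(1)] / rec$data[pz, t_peak(4)], 3,
               tolerance = 1e-6)
  # frontal weight far below the Pz weight
  expect_lt(rec$data[fp1, t_peak(1)], 0.1 * rec$data[pz, t_peak(1)])
})

test_that("the burst's spectral peak matches the configured ERO frequency", {
  fs <- 500
  times <- seq(-2, 5 - 1 / fs, by = 1 / fs)
  for (f in c(3, 5)) {
    ep <- make_epochs(array(burst_trace(times, 0.35, f), c(1, 1, length(times))),
                      sfreq = fs, tmin = -2, ch_names = "Pz")
    # template readout is exact; the raw spectral argmax carries the shallow-
    # top bias of a ~1.3-cycle burst and is held to a looser bound
    expect_lt(abs(estimate_stim_frequency(ep, 350,
                                          method = "matched")$stim_frequency -
                  f), 0.11)
    expect_lt(abs(estimate_stim_frequency(ep, 350,
                                          method = "evoked")$stim_frequency -
                  f), 0.5)
  }
})

test_that("white noise degrades single-trial SNR but not the grand average", {
  sq <- generate_sequence(100, 0.25, seed = 4)
  spec <- recording_spec(sampling_rate = 250)
  truth <- erp_ground_truth(n700_amplitude = 0)
  grand <- function(sd_w) {
    rec <- simulate_recording(spec, sq, truth,
                              noise_spec(0, 0, 0, sd_w, 0, 0), seed = 6)
    ep <- epoch_recording(rec, c(-0.2, 0.8), baseline = c(-0.2, 0),
                          events = rec$events[rec$events$trial_type == "target", ])
    pz <- match("Pz", ep$ch_names)
    avg <- colMeans(ep$data)[pz, ]
    snr_trial <- mean(abs(ep$data[, pz, which.min(abs(ep$times - 0.35))]))
    list(avg_peak = max(avg), resid = stats::sd(ep$data[, pz, 1]))
  }
  g0 <- grand(1); g1 <- grand(8)
  # single-trial noise grows with white_noise_sd
  expect_gt(g1$resid, 3 * g0$resid)
  # the grand-average peak expectation is unchanged (100-trial average)
  expect_equal(g1$avg_peak, g0$avg_peak, tolerance = 0.5)
})

test_that("behavioral generator matches its probability model", {
  sq <- generate_sequence(400, 0.25, seed = 2)
  clean <- simulate_behavior(sq, behavior_ground_truth(p_omission = 0,
                                                       p_commission = 0),
                             seed = 1)
  v <- score_vot(clean)
  expect_equal(v$omission_rate, 0)
  expect_equal(v$commission_rate, 0)

  # binomial oracle: omissions over repeated draws average p * n_targets
  counts <- vapply(1:60, function(s) {
    b <- simulate_behavior(sq, behavior_ground_truth(p_omission = 0.2),
                           seed = s)
    sum(b$trial_type == "target" & b$response != b$tilt)
  }, 0)
  expect_equal(mean(counts), 20, tolerance = 1.5)  # 3 SE of binomial mean

  # degenerate RT scale: zero variability
  b0 <- simulate_behavior(sq, behavior_ground_truth(rt_scale = 0), seed = 3)
  expect_equal(score_vot(b0)$rt_variability, 0)
})

test_that("crossover studies counterbalance order and ledger the ground truth", {
  st <- simulate_crossover_study(n_subjects = 20, seed = 5,
                                 keep_recordings = FALSE, n_trials = 8)
  expect_equal(sum(st$ledger$order == "actual"), 10)
  expect_equal(nrow(st$ledger), 20)
  expect_true(all(c("p300_latency_ms", "ero_frequency_hz",
                    "delta_p300_actual", "delta_omission_sham") %in%
                  names(st$ledger)))
  expect_error(simulate_crossover_study(n_subjects = 1), "n_subjects")
  # mirrored analyzed sample size
  st19 <- simulate_crossover_study(n_subjects = 19, seed = 5,
                                   keep_recordings = FALSE, n_trials = 8)
  expect_equal(length(st19$subjects), 19)
  expect_equal(sum(st19$ledger$order == "actual"), 10)
})
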