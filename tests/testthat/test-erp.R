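# Offline ERP pipeline: merging, interpolation, trial-by-trial rejection
# boundaries, averaging, and window measures.

test_that("merging preserves events and reconciles sampling rates", {
  sq <- generate_sequence(12, 0.25, seed = 3)
  tr <- erp_ground_truth()
  pre <- simulate_recording(recording_spec(sampling_rate = 500), sq, tr,
                            silent_noise(), seed = 1)
  post <- simulate_recording(recording_spec(sampling_rate = 250), sq, tr,
                             silent_noise(), seed = 2)
  merged <- preprocess_offline(pre, post)
  expect_equal(merged$sfreq, 250)
  expect_equal(nrow(merged$events), 24)
  expect_equal(sum(merged$events$block == "pre"), 12)
  # post events shifted beyond the pre block
  expect_true(all(merged$events$onset[merged$events$block == "post"] >
                  p300tacs:::rec_duration(pre)))
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  labels <- default_channels()
  pos <- standard_montage(labels)
  # smooth synthetic field: low-order polynomial of position + time modulation
  n <- 200
  field <- outer(0.8 * pos$z + 0.5 * pos$y - 0.3 * pos$x * pos$y,
                 sin(seq_len(n) / 15))
  interp <- spline_interpolate(field, labels, "Pz")
  pz <- match("Pz", labels)
  expect_gt(stats::cor(interp[pz, ], field[pz, ]), 0.9)
  expect_equal(interp[-pz, ], field[-pz, ])   # other channels untouched

  # >3 bad channels: proceed with a warning
  sq <- generate_sequence(8, 0.25, seed = 1)
  rec <- simulate_recording(recording_spec(sampling_rate = 250), sq,
                            erp_ground_truth(), noise_spec(), seed = 1)
  expect_warning(preprocess_offline(rec, rec,
                                    bad_channels = c("Fp1", "Fp2", "F3", "F4")),
                 "at most 3")
})

test_that("marked artifact segments are excised with their events", {
  sq <- generate_sequence(12, 0.25, seed = 3)
  rec <- simulate_recording(recording_spec(sampling_rate = 250), sq,
                            erp_ground_truth(), silent_noise(), seed = 1)
  victim <- rec$events$onset[5]
  merged <- preprocess_offline(rec, rec, exclude_segments = data.frame(
    start = victim - 0.2, end = victim + 0.6))
  expect_equal(nrow(merged$events), 23)
  expect_false(any(merged$events$block == "pre" &
                   abs(merged$events$onset - victim) < 1e-9))
})

test_that("trial-by-trial rejection honors its strict boundaries", {
  set.seed(4)
  labels <- default_channels()
  nt <- 100; nc <- 22; ns <- 100
  base <- array(rnorm(nt * nc * ns, sd = 1), c(nt, nc, ns))
  cfg <- offline_config()

  # clean data passes through untouched
  ep <- make_epochs(base, ch_names = labels)
  out <- tbt_reject(ep, cfg)
  expect_equal(out$data, ep$data)
  expect_equal(length(attr(out, "excluded_channels")), 0)

  # one channel exceeding 150 uV in exactly 20% of epochs -> globally excluded
  arr <- base
  arr[1:20, 5, 50] <- arr[1:20, 5, 50] + 500
  out2 <- tbt_reject(make_epochs(arr, ch_names = labels), cfg)
  expect_equal(attr(out2, "excluded_channels"), labels[5])

  # exactly at 15% (and exactly 150 uV peak-to-peak) stays: strict inequality
  arr3 <- array(0, c(20, nc, ns))
  arr3[1:3, 7, ] <- 75                     # ptp exactly 150 via -75/+75
  arr3[1:3, 7, 1] <- -75
  out3 <- tbt_reject(make_epochs(arr3, ch_names = labels), cfg)
  expect_equal(length(attr(out3, "excluded_channels")), 0)
  expect_equal(p300tacs:::n_trials(out3), 20)

  # 11 bad channels -> epoch dropped; 10 -> retained and repaired
  arr4 <- base
  arr4[3, 1:11, 60] <- arr4[3, 1:11, 60] + 400
  arr4[4, 1:10, 60] <- arr4[4, 1:10, 60] + 400
  out4 <- tbt_reject(make_epochs(arr4, ch_names = labels), cfg)
  expect_true(3 %in% out4$rejected)
  expect_false(4 %in% out4$rejected)
  # epoch 4's bad channels were repaired (no 400 uV excursions left)
  i4 <- which(out4$kept == 4)
  expect_lt(max(abs(out4$data[i4, 1:10, ])), 150)
  # untouched channels in retained epochs are bit-identical
  expect_identical(out4$data[i4, 12:22, ], arr4[4, 12:22, ])
})

test_that("ERP averaging and window measures follow their definitions", {
  labels <- default_channels()
  cfg <- offline_config()
  # constant 1 uV epochs (baseline already zero-mean by construction)
  ns <- 500; times0 <- -0.5 + (seq_len(ns) - 1) / 250
  arr <- array(rep(1, 20 * 22 * ns), c(20, 22, ns))
  ep <- make_epochs(arr, ch_names = labels)
  erp <- compute_erp(ep, cfg)
  expect_equal(erp$p300_mean, 1)
  expect_equal(erp$p300_max, 1)
  expect_equal(erp$late_mean, 1)
  expect_equal(measure_late_erp(erp, cfg), 1)
  expect_equal(erp$n_epochs, 20)

  # max >= mean on identical windows
  set.seed(6)
  arr2 <- array(rnorm(20 * 22 * ns), c(20, 22, ns))
  erp2 <- compute_erp(make_epochs(arr2, ch_names = labels),
                      offline_config(p300_mean_window = c(250, 550)))
  expect_gte(erp2$p300_max, erp2$p300_mean)

  # averaging linearity: grand average = weighted mean of subset averages
  a <- compute_erp(make_epochs(arr2[1:8, , , drop = FALSE], ch_names = labels), cfg)
  b <- compute_erp(make_epochs(arr2[9:20, , , drop = FALSE], ch_names = labels), cfg)
  ab <- compute_erp(make_epochs(arr2, ch_names = labels), cfg)
  expect_equal((8 * a$average + 12 * b$average) / 20, ab$average)
})

test_that("target ERPs exceed standard ERPs at the design's trial counts", {
  # two sessions x pre/post, full 400-trial blocks, reduced montage; the
  # mean-amplitude contrast needs the pooled epoch counts the study provides
  spec <- recording_spec(channel_labels = c("Fz", "Cz", "C3", "C4",
                                            "Pz", "POz"),
                         sampling_rate = 250)
  truth <- erp_ground_truth(
    topography_weights = default_topography(spec$channel_labels))
  mean_diff <- 0; n_blocks <- 0
  for (s in 1:2) {
    sq <- generate_sequence(400, 0.25, seed = 30 + s)
    pre <- simulate_recording(spec, sq, truth, noise_spec(), seed = 40 + s)
    post <- simulate_recording(spec, sq, truth, noise_spec(), seed = 50 + s)
    erps <- erp_by_condition(preprocess_offline(pre, post))
    for (bl in c("pre", "post")) {
      # maximum-peak contrast: strong at single-block scale
      expect_gt(erps[[bl]]$target$p300_max, erps[[bl]]$standard$p300_max)
      mean_diff <- mean_diff +
        (erps[[bl]]$target$p300_mean - erps[[bl]]$standard$p300_mean)
      n_blocks <- n_blocks + 1
    }
  }
  expect_gt(mean_diff / n_blocks, 0)    # pooled mean-amplitude contrast
})

test_that("the measured amplitudes scale linearly with the input signal", {
  sq <- generate_sequence(40, 0.25, seed = 9)
  spec <- recording_spec(sampling_rate = 250)
  rec_pre <- simulate_recording(spec, sq, erp_ground_truth(), noise_spec(),
                                seed = 10)
  rec_post <- simulate_recording(spec, sq, erp_ground_truth(), noise_spec(),
                                 seed = 11)
  erps <- erp_by_condition(preprocess_offline(rec_pre, rec_post))
  rec_scaled <- rec_pre; rec_scaled$data <- 2 * rec_scaled$data
  rec_scaled2 <- rec_post; rec_scaled2$data <- 2 * rec_scaled2$data
  erps2 <- erp_by_condition(preprocess_offline(rec_scaled, rec_scaled2))
  expect_equal(erps2$pre$target$p300_mean, 2 * erps$pre$target$p300_mean,
               tolerance = 1e-6)
  expect_equal(erps2$post$target$late_mean, 2 * erps$post$target$late_mean,
               tolerance = 1e-6)
})

test_that("late-window injections are measured where they were placed", {
  sq <- generate_sequence(20, 0.25, seed = 13)
  spec <- recording_spec(sampling_rate = 250)
  mk <- function(shift) simulate_recording(
    spec, sq, erp_ground_truth(n700_window_shift = shift, n700_amplitude = -2),
    silent_noise(), seed = 1)
  out <- analyze_session(mk(0), mk(1), tfr_cfg = NULL, trial_types = "target")
  val <- function(m, b) out$value[out$measure == m & out$block == b]
  # injected late change recovered near unit gain; P300 window unaffected
  expect_equal(val("late_erp_mean", "post") - val("late_erp_mean", "pre"), 1,
               tolerance = 0.12)
  expect_lt(abs(val("p300_mean", "post") - val("p300_mean", "pre")), 0.1)
  # the configured late component is negative in the late window
  expect_lt(val("late_erp_mean", "pre"), 0)
})
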