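# Synthetic EEG / behavior generator.
#
# The generator embodies the event-related-oscillation account of the P300:
# every stimulus adds a Gaussian-windowed burst of the individual delta/theta
# frequency whose largest positive half-wave is the P300, plus (for targets) a
# late negative deflection around 800 ms. Background activity is 1/f +
# 10 Hz alpha + white sensor noise, with occasional high-amplitude transients
# so the artifact-rejection stages have work to do.

#' Recording specification
#'
#' @param channel_labels 10/20 labels; must be unique and contain Pz.
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param duration recording length in seconds (may be `NULL` when derived
#'   from a sequence by [simulate_recording()]).
#' @export
recording_spec <- function(channel_labels = default_channels(),
                           sampling_rate = 500, duration = NULL) {
  assert_that(sampling_rate > 0, "sampling_rate must be > 0")
  assert_that(!anyDuplicated(channel_labels), "channel labels must be unique")
  assert_that("Pz" %in% channel_labels, "Pz (analysis channel) must be present")
  standard_montage(channel_labels)  # validates labels
  structure(list(channel_labels = channel_labels,
                 n_channels = length(channel_labels),
                 sampling_rate = sampling_rate, duration = duration),
            class = "recording_spec")
}

#' Default scalp topography of the simulated P300
#'
#' Smooth centro-parietal field: Gaussian in angular distance from Pz with
#' `width_deg` standard deviation. The mean weight across the montage is kept
#' small so common-average referencing attenuates Pz amplitudes only mildly.
#'
#' @param channel_labels channel labels.
#' @param width_deg angular width (degrees) of the field.
#' @export
default_topography <- function(channel_labels = default_channels(),
                               width_deg = 32) {
  pos <- standard_montage(channel_labels)
  pz <- as.numeric(pos[pos$label == "Pz", c("x", "y", "z")])
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  ang <- acos(pmin(pmax(xyz %*% pz, -1), 1)) * 180 / pi
  w <- exp(-(ang / width_deg)^2 / 2)
  stats::setNames(as.numeric(w), channel_labels)
}

#' ERP ground truth for the generator
#'
#' `p300_amplitude` is the burst's peak amplitude at Pz in microvolts;
#' `*_window_shift` parameters add slow components normalized to unit *mean*
#' amplitude over the corresponding analysis window at Pz, so pre-to-post
#' intervention effects are expressed directly in outcome units.
#'
#' @param p300_latency P300 latency in ms post-stimulus (200-600).
#' @param ero_frequency individual delta/theta frequency in Hz (1-8).
#' @param p300_amplitude burst peak amplitude at Pz, microvolts.
#' @param n700_amplitude late negative component amplitude (microvolts,
#'   negative) centered around 800 ms; targets only.
#' @param topography_weights named per-channel scaling in `[0, 1]`.
#' @param target_standard_ratio amplitude ratio target / standard (> 1).
#' @param p300_window_shift additive mean-window (200-550 ms) amplitude
#'   change, microvolts (used for post-intervention blocks).
#' @param n700_window_shift additive mean-window (700-1000 ms) change.
#' @param ero_log10_gain log10 power gain applied to the burst.
#' @export
erp_ground_truth <- function(p300_latency = 350, ero_frequency = 4,
                             p300_amplitude = 5, n700_amplitude = -1.5,
                             topography_weights = default_topography(),
                             target_standard_ratio = 3,
                             p300_window_shift = 0, n700_window_shift = 0,
                             ero_log10_gain = 0) {
  assert_that(p300_latency >= 200 && p300_latency <= 600,
              "p300_latency must lie in [200, 600] ms")
  assert_that(ero_frequency >= 1 && ero_frequency <= 8,
              "ero_frequency must lie in [1, 8] Hz")
  assert_that(target_standard_ratio > 1, "target_standard_ratio must be > 1")
  assert_that(all(topography_weights >= 0 & topography_weights <= 1),
              "topography weights must lie in [0, 1]")
  structure(list(p300_latency = p300_latency, ero_frequency = ero_frequency,
                 p300_amplitude = p300_amplitude,
                 n700_amplitude = n700_amplitude,
                 topography_weights = topography_weights,
                 target_standard_ratio = target_standard_ratio,
                 p300_window_shift = p300_window_shift,
                 n700_window_shift = n700_window_shift,
                 ero_log10_gain = ero_log10_gain),
            class = "erp_ground_truth")
}

#' Background-noise specification
#'
#' @param one_over_f_exponent spectral exponent of the 1/f background.
#' @param one_over_f_amplitude RMS amplitude (microvolts) of the 1/f noise.
#' @param alpha_amplitude amplitude (microvolts) of the 10 Hz alpha rhythm.
#' @param white_noise_sd white sensor-noise SD, microvolts.
#' @param artifact_rate fraction of trials carrying a high-amplitude transient.
#' @param artifact_amplitude transient amplitude, microvolts.
#' @export
noise_spec <- function(one_over_f_exponent = 1, one_over_f_amplitude = 8,
                       alpha_amplitude = 5, white_noise_sd = 2,
                       artifact_rate = 0.03, artifact_amplitude = 250) {
  vals <- c(one_over_f_exponent, one_over_f_amplitude, alpha_amplitude,
            white_noise_sd, artifact_rate, artifact_amplitude)
  assert_that(all(vals >= 0), "noise parameters must be non-negative")
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 one_over_f_amplitude = one_over_f_amplitude,
                 alpha_amplitude = alpha_amplitude,
                 white_noise_sd = white_noise_sd,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude),
            class = "noise_spec")
}

#' Intervention effect specification
#'
#' Pre-to-post changes per intervention, in outcome units: ERP shifts in
#' microvolts of window-mean amplitude at Pz, oscillatory power in log10
#' units, behavior as probability deltas. The defaults reproduce the study's
#' findings qualitatively: a null P300 interaction (equal decrease under both
#' interventions), a late-ERP increase mainly under actual stimulation, a
#' small ERO power decrease in both, and omission rates worsening post-block
#' under both interventions (fatigue). `sd_delta_*` are between-subject SDs
#' of the realized change scores.
#'
#' @param delta_p300_actual,delta_p300_sham P300 mean-amplitude change, uV.
#' @param delta_n700_actual,delta_n700_sham late-ERP mean-amplitude change, uV.
#' @param delta_ero_actual,delta_ero_sham burst log10-power change.
#' @param delta_omission,delta_commission probability change post vs pre.
#' @param delta_rt median reaction-time change in seconds.
#' @param sd_delta_erp,sd_delta_ero,sd_delta_omission between-subject SDs.
#' @export
effect_spec <- function(delta_p300_actual = -0.28, delta_p300_sham = -0.28,
                        delta_n700_actual = 0.80, delta_n700_sham = 0.26,
                        delta_ero_actual = -0.05, delta_ero_sham = -0.05,
                        delta_omission = 0.09, delta_commission = 0.01,
                        delta_rt = 0,
                        sd_delta_erp = 0.8, sd_delta_ero = 0.1,
                        sd_delta_omission = 0.06) {
  structure(as.list(environment()), class = "effect_spec")
}

#' Behavioral ground truth
#'
#' @param rt_location median reaction time in seconds (lognormal location).
#' @param rt_scale lognormal scale (log-SD); 0 makes all RTs identical.
#' @param p_omission probability that a target gets no correct target-key
#'   response (split between wrong-key presses and omitted presses).
#' @param p_commission probability of a target-key response to a standard.
#' @param wrong_key_share share of omission errors that are wrong-key presses
#'   rather than missing responses.
#' @export
behavior_ground_truth <- function(rt_location = 0.45, rt_scale = 0.25,
                                  p_omission = 0.18, p_commission = 0.05,
                                  wrong_key_share = 0.5) {
  assert_that(all(c(p_omission, p_commission, wrong_key_share) >= 0 &
                  c(p_omission, p_commission, wrong_key_share) <= 1),
              "probabilities must lie in [0, 1]")
  assert_that(rt_scale >= 0 && rt_location > 0, "invalid RT parameters")
  structure(as.list(environment()), class = "behavior_ground_truth")
}

# ---- waveform building blocks ----------------------------------------------

# ERO burst: cosine at `freq` under a Gaussian envelope with sigma = T/4, so
# the largest positive half-wave peaks at `latency` with unit amplitude.
ero_burst <- function(t, latency, freq) {
  sigma <- 1 / (4 * freq)
  cos(2 * pi * freq * (t - latency)) * exp(-(t - latency)^2 / (2 * sigma^2))
}

# Late negative component: Gaussian centred at 800 ms.
n700_bump <- function(t, center = 0.8, sigma = 0.12) {
  exp(-(t - center)^2 / (2 * sigma^2))
}

# Zero-mean (Ricker-shaped) slow component whose central lobe fills the
# half-open analysis window [w1, w2), normalized so its mean over that window
# at Pz *after common-average referencing* is exactly one: effect units equal
# the window-mean amplitude the ERP stage reports. A zero-area shape passes
# the offline band filters at unit gain, unlike a monophasic bump whose DC
# mass the 0.5 Hz high-pass removes.
window_component <- function(t, w1, w2, fs, car_gain = 1) {
  center <- (w1 + w2) / 2
  sigma <- (w2 - w1) / 3.3
  shape <- function(x) {
    u <- (x - center) / sigma
    (1 - u^2) * exp(-u^2 / 2)
  }
  tw <- seq(round(w1 * fs), round(w2 * fs) - 1) / fs
  shape(t) / (mean(shape(tw)) * car_gain)
}

# FFT-shaped 1/f noise, normalized to unit SD per channel. A non-Hermitian
# random spectrum yields two independent real noises (real and imaginary part
# of one inverse FFT), so channels are generated in pairs.
colored_noise_matrix <- function(nch, n, fs, exponent) {
  nfft <- 2^ceiling(log2(n))
  f <- (0:(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f)
  scale <- c(0, f[-1]^(-exponent / 2))
  out <- matrix(0, nch, n)
  for (i in seq(1, nch, by = 2)) {
    spec <- (stats::rnorm(nfft) + 1i * stats::rnorm(nfft)) * scale
    z <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
    x1 <- Re(z)
    out[i, ] <- x1 / stats::sd(x1)
    if (i + 1 <= nch) {
      x2 <- Im(z)
      out[i + 1, ] <- x2 / stats::sd(x2)
    }
  }
  out
}

# ---- main generator ---------------------------------------------------------

#' Simulate a continuous oddball EEG recording
#'
#' Each stimulus adds a Gaussian-windowed burst of `truth$ero_frequency`
#' peaking at `truth$p300_latency` (amplitude scaled per channel by the
#' topography and by trial type), plus a late negative deflection for targets;
#' any configured pre-to-post effect components are added as window-normalized
#' slow deflections. Identical seeds give byte-identical output.
#'
#' @param spec a [recording_spec()]; if `spec$duration` is `NULL` it is set to
#'   the last onset + 6.5 s.
#' @param sequence a [generate_sequence()] result (or any data.frame with
#'   `onset`, `trial_type`).
#' @param truth an [erp_ground_truth()].
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return an [eeg_recording()]; events carry `trial_type`, `tilt`, `duration`.
#' @export
simulate_recording <- function(spec = recording_spec(), sequence,
                               truth = erp_ground_truth(),
                               noise = noise_spec(), seed = 1) {
  fs <- spec$sampling_rate
  duration <- spec$duration %||% (max(sequence$onset) + 6.5)
  assert_that(max(sequence$onset) + 1.2 <= duration,
              "sequence onsets do not fit within the recording duration")
  labels <- spec$channel_labels
  w <- truth$topography_weights
  assert_that(all(labels %in% names(w)),
              "topography weights missing for some channels")
  w <- w[labels]

  n <- as.integer(round(duration * fs)) + 1L
  tvec <- (seq_len(n) - 1L) / fs
  nch <- length(labels)

  with_seed(seed, {
    data <- matrix(0, nch, n)
    if (noise$one_over_f_amplitude > 0) {
      data <- data + noise$one_over_f_amplitude *
        colored_noise_matrix(nch, n, fs, noise$one_over_f_exponent)
    }
    if (noise$alpha_amplitude > 0) {
      carrier <- sin(2 * pi * 10 * tvec)
      carrier_q <- cos(2 * pi * 10 * tvec)
      for (c_i in seq_len(nch)) {
        ph <- stats::runif(2, 0, 2 * pi)
        mod <- 0.6 + 0.4 * sin(2 * pi * 0.1 * tvec + ph[1])
        data[c_i, ] <- data[c_i, ] + noise$alpha_amplitude * mod *
          (cos(ph[2]) * carrier + sin(ph[2]) * carrier_q)
      }
    }
    if (noise$white_noise_sd > 0) {
      data <- data + matrix(stats::rnorm(nch * n, sd = noise$white_noise_sd),
                            nch, n)
    }

    # event-locked components (evaluated on the local support only);
    # common-average referencing downstream scales Pz by (1 - mean weight)
    car_gain <- 1 - mean(w)
    f <- truth$ero_frequency
    burst_gain <- 10^(truth$ero_log10_gain / 2)
    lat <- truth$p300_latency / 1000
    for (i in seq_len(nrow(sequence))) {
      on <- sequence$onset[i]
      is_target <- sequence$trial_type[i] == "target"
      amp <- truth$p300_amplitude * burst_gain *
        (if (is_target) 1 else 1 / truth$target_standard_ratio)
      i0 <- max(1L, time_to_sample(on - 0.2, fs))
      i1 <- min(n, time_to_sample(on + 1.3, fs))
      tt <- tvec[i0:i1] - on
      comp <- amp * ero_burst(tt, lat, f)
      if (is_target) {
        comp <- comp + truth$n700_amplitude * n700_bump(tt)
        if (truth$p300_window_shift != 0) {
          comp <- comp + truth$p300_window_shift *
            window_component(tt, 0.20, 0.55, fs, car_gain)
        }
        if (truth$n700_window_shift != 0) {
          comp <- comp + truth$n700_window_shift *
            window_component(tt, 0.70, 1.00, fs, car_gain)
        }
      }
      data[, i0:i1] <- data[, i0:i1] + outer(w, comp)
    }

    # high-amplitude transients on a random subset of trials
    if (noise$artifact_rate > 0 && noise$artifact_amplitude > 0) {
      hit <- which(stats::runif(nrow(sequence)) < noise$artifact_rate)
      for (i in hit) {
        chans <- sample(nch, sample(1:3, 1))
        t0 <- sequence$onset[i] + stats::runif(1, -0.3, 0.8)
        i0 <- max(1L, time_to_sample(t0, fs))
        i1 <- min(n, i0 + as.integer(0.2 * fs))
        pulse <- noise$artifact_amplitude *
          sin(pi * seq(0, 1, length.out = i1 - i0 + 1))^2
        data[chans, i0:i1] <- data[chans, i0:i1] +
          matrix(pulse, length(chans), length(pulse), byrow = TRUE)
      }
    }

    events <- data.frame(onset = sequence$onset,
                         duration = rep(0.5, nrow(sequence)),
                         trial_type = sequence$trial_type,
                         tilt = sequence$tilt %||% NA_character_,
                         stringsAsFactors = FALSE)
    eeg_recording(data, labels, fs, events)
  })
}

#' Simulate oddball response behavior
#'
#' One row per trial: response side (`left` / `right` / `none`) and reaction
#' time in seconds (`NA` when no key was pressed). Targets fail to receive the
#' correct target key with probability `p_omission` (split between wrong-key
#' presses and missing responses); standards receive the target key with
#' probability `p_commission`.
#'
#' @param sequence a [generate_sequence()] result.
#' @param truth a [behavior_ground_truth()].
#' @param seed integer seed.
#' @return data.frame `trial`, `trial_type`, `tilt`, `response`, `rt`.
#' @export
simulate_behavior <- function(sequence, truth = behavior_ground_truth(),
                              seed = 1) {
  n <- nrow(sequence)
  with_seed(seed, {
    correct <- sequence$tilt
    wrong <- ifelse(correct == "left", "right", "left")
    is_target <- sequence$trial_type == "target"
    u_err <- stats::runif(n)
    u_kind <- stats::runif(n)
    resp <- correct
    om <- is_target & u_err < truth$p_omission
    resp[om & u_kind < truth$wrong_key_share] <-
      wrong[om & u_kind < truth$wrong_key_share]
    resp[om & u_kind >= truth$wrong_key_share] <- "none"
    com <- !is_target & u_err < truth$p_commission
    resp[com] <- wrong[com]
    rt <- ifelse(resp == "none", NA_real_,
                 truth$rt_location * exp(truth$rt_scale * stats::rnorm(n)))
    data.frame(trial = seq_len(n), trial_type = sequence$trial_type,
               tilt = sequence$tilt, response = resp, rt = rt,
               stringsAsFactors = FALSE)
  })
}

# Apply an intervention's pre-to-post effects to a subject's ground truth.
apply_effects <- function(truth, behavior, deltas) {
  post_truth <- truth
  post_truth$p300_window_shift <- truth$p300_window_shift + deltas$p300
  post_truth$n700_window_shift <- truth$n700_window_shift + deltas$n700
  post_truth$ero_log10_gain <- truth$ero_log10_gain + deltas$ero
  post_beh <- behavior
  post_beh$p_omission <- min(max(behavior$p_omission + deltas$omission, 0), 1)
  post_beh$p_commission <- min(max(behavior$p_commission + deltas$commission, 0), 1)
  post_beh$rt_location <- max(behavior$rt_location + deltas$rt, 0.05)
  list(truth = post_truth, behavior = post_beh)
}

#' Simulate a complete two-intervention crossover study
#'
#' Draws per-subject ERP and behavioral ground truth (random effects around
#' the population defaults), counterbalances intervention order (half the
#' sample receives actual stimulation first), and generates pre/post
#' recordings and behavior for both interventions. Every ground-truth
#' parameter, including the realized per-subject change scores, is stored in
#' the returned ledger for recovery tests.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @param spec a [recording_spec()].
#' @param noise a [noise_spec()].
#' @param n_trials,p_target,isi_range oddball design per block.
#' @param keep_recordings if `FALSE`, recordings are dropped after generation
#'   (ledger and behavior only) - useful for behavioral-scale simulations.
#' @return list with `subjects` (each: `id`, `order`, `truth`, `behavior`,
#'   `deltas`, `sessions$<actual|sham>$<pre|post>` holding `recording`,
#'   `behavior`, `sequence`) and `ledger` (data.frame of all parameters).
#' @export
simulate_crossover_study <- function(n_subjects = 19, effects = effect_spec(),
                                     seed = 1, spec = recording_spec(),
                                     noise = noise_spec(), n_trials = 400,
                                     p_target = 0.25, isi_range = c(1, 2.5),
                                     keep_recordings = TRUE) {
  assert_that(n_subjects >= 2, "n_subjects must be >= 2 (statistics undefined)")
  seeds <- child_seeds(seed, n_subjects + 1L)
  order_first <- with_seed(seeds[n_subjects + 1L], {
    first <- rep("sham", n_subjects)
    first[sample(n_subjects, round(n_subjects / 2))] <- "actual"
    first
  })

  subjects <- vector("list", n_subjects)
  ledger <- NULL
  for (s in seq_len(n_subjects)) {
    sseed <- seeds[s]
    draws <- with_seed(sseed, {
      list(
        latency = min(max(stats::rnorm(1, 350, 30), 270), 430),
        freq = stats::runif(1, 2, 7),
        amp = max(stats::rnorm(1, 5, 1), 2),
        n700 = min(stats::rnorm(1, -1.5, 0.4), -0.5),
        p_om = stats::plogis(stats::qlogis(0.18) + stats::rnorm(1, 0, 0.35)),
        p_com = stats::plogis(stats::qlogis(0.05) + stats::rnorm(1, 0, 0.3)),
        rt_loc = 0.45 * exp(stats::rnorm(1, 0, 0.15)),
        noise_delta = stats::rnorm(6),
        beh_delta = stats::rnorm(4),
        block_seeds = sample.int(.Machine$integer.max - 1L, 8)
      )
    })
    truth <- erp_ground_truth(
      p300_latency = draws$latency, ero_frequency = draws$freq,
      p300_amplitude = draws$amp, n700_amplitude = draws$n700,
      topography_weights = default_topography(spec$channel_labels))
    behavior <- behavior_ground_truth(rt_location = draws$rt_loc,
                                      p_omission = draws$p_om,
                                      p_commission = draws$p_com)

    deltas <- list(
      actual = list(
        p300 = effects$delta_p300_actual + effects$sd_delta_erp * draws$noise_delta[1],
        n700 = effects$delta_n700_actual + effects$sd_delta_erp * draws$noise_delta[2],
        ero = effects$delta_ero_actual + effects$sd_delta_ero * draws$noise_delta[3],
        omission = effects$delta_omission + effects$sd_delta_omission * draws$beh_delta[1],
        commission = effects$delta_commission,
        rt = effects$delta_rt),
      sham = list(
        p300 = effects$delta_p300_sham + effects$sd_delta_erp * draws$noise_delta[4],
        n700 = effects$delta_n700_sham + effects$sd_delta_erp * draws$noise_delta[5],
        ero = effects$delta_ero_sham + effects$sd_delta_ero * draws$noise_delta[6],
        omission = effects$delta_omission + effects$sd_delta_omission * draws$beh_delta[2],
        commission = effects$delta_commission,
        rt = effects$delta_rt))

    sessions <- list()
    k <- 1
    for (iv in c("actual", "sham")) {
      post <- apply_effects(truth, behavior, deltas[[iv]])
      blocks <- list()
      for (bl in c("pre", "post")) {
        bseed <- draws$block_seeds[k]; k <- k + 1
        sq <- generate_sequence(n_trials = n_trials, p_target = p_target,
                                isi_range = isi_range, seed = bseed)
        tr <- if (bl == "pre") truth else post$truth
        bh <- if (bl == "pre") behavior else post$behavior
        rec <- if (keep_recordings)
          simulate_recording(spec, sq, tr, noise, seed = bseed) else NULL
        blocks[[bl]] <- list(recording = rec,
                             behavior = simulate_behavior(sq, bh, seed = bseed + 1),
                             sequence = sq)
      }
      sessions[[iv]] <- blocks
    }

    subjects[[s]] <- list(id = sprintf("sub-%02d", s), order = order_first[s],
                          truth = truth, behavior = behavior,
                          deltas = deltas, sessions = sessions)
    ledger <- rbind(ledger, data.frame(
      subject = sprintf("sub-%02d", s), order = order_first[s],
      p300_latency_ms = draws$latency, ero_frequency_hz = draws$freq,
      p300_amplitude_uv = draws$amp, n700_amplitude_uv = draws$n700,
      p_omission = draws$p_om, p_commission = draws$p_com,
      rt_location_s = draws$rt_loc,
      delta_p300_actual = deltas$actual$p300, delta_p300_sham = deltas$sham$p300,
      delta_n700_actual = deltas$actual$n700, delta_n700_sham = deltas$sham$n700,
      delta_ero_actual = deltas$actual$ero, delta_ero_sham = deltas$sham$ero,
      delta_omission_actual = deltas$actual$omission,
      delta_omission_sham = deltas$sham$omission))
  }
  list(subjects = subjects, ledger = ledger, effects = effects, seed = seed)
}
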