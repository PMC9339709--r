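# Simulation studies: parameter-recovery and calibration experiments run by
# the analysis scripts, the test suite, and the acceptance script. Problem
# sizes are arguments so the studies scale; defaults are the sizes the
# package's own reports use.

#' Online parameter-recovery study
#'
#' Simulates pre-intervention oddball blocks for `n_subjects` with random
#' individual P300 latencies (normal around 350 ms), ERO frequencies
#' (uniform 2-7 Hz) and late-component amplitudes, runs the full online chain
#' ([estimate_stim_params()]) at default background noise, and returns the
#' estimation errors.
#'
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed.
#' @param sampling_rate recording rate in Hz (mobile EEG systems record at
#'   250-500 Hz; the study default uses 250 Hz).
#' @param n_trials oddball trials per block (protocol: 400).
#' @param noise a [noise_spec()].
#' @return data.frame `subject`, `true_latency_ms`, `est_latency_ms`,
#'   `true_freq_hz`, `est_freq_hz`, `lat_err_ms`, `freq_err_hz`.
#' @export
online_recovery_sim <- function(n_subjects = 50, seed = 1,
                                sampling_rate = 250, n_trials = 400,
                                noise = noise_spec()) {
  seeds <- child_seeds(seed, n_subjects)
  spec <- recording_spec(sampling_rate = sampling_rate)
  out <- NULL
  for (s in seq_len(n_subjects)) {
    draws <- with_seed(seeds[s], list(
      lat = min(max(stats::rnorm(1, 350, 30), 270), 430),
      f = stats::runif(1, 2, 7),
      n7 = min(stats::rnorm(1, -1.5, 0.4), -0.5),
      sq_seed = sample.int(2^30, 1), rec_seed = sample.int(2^30, 1)))
    sq <- generate_sequence(n_trials = n_trials, seed = draws$sq_seed)
    truth <- erp_ground_truth(p300_latency = draws$lat,
                              ero_frequency = draws$f,
                              n700_amplitude = draws$n7)
    rec <- simulate_recording(spec, sq, truth, noise, seed = draws$rec_seed)
    par <- estimate_stim_params(rec)
    out <- rbind(out, data.frame(
      subject = s, true_latency_ms = draws$lat,
      est_latency_ms = par$p300_latency_ms,
      true_freq_hz = draws$f, est_freq_hz = par$stim_frequency_hz,
      lat_err_ms = par$p300_latency_ms - draws$lat,
      freq_err_hz = par$stim_frequency_hz - draws$f))
  }
  out
}

# Reduced montage used by the replicated crossover simulations (the outcome
# is measured at Pz; a centro-parietal subset keeps the common-average
# reference meaningful at a fraction of the cost).
reduced_montage <- function() c("Fz", "Cz", "C3", "C4", "Pz", "POz")

# One simulated crossover study analyzed through the offline ERP stage,
# returning the per-measure interaction estimate (mean over subjects of the
# within-subject interaction contrast) and its ANOVA.
.run_erp_study <- function(n_subjects, effects, seed, spec, n_trials,
                           measures = "p300_mean") {
  st <- simulate_crossover_study(n_subjects = n_subjects, effects = effects,
                                 seed = seed, spec = spec,
                                 n_trials = n_trials)
  cfg <- offline_config(resample_rate = min(250, spec$sampling_rate))
  outcomes <- NULL
  for (sub in st$subjects) {
    for (iv in c("actual", "sham")) {
      s <- sub$sessions[[iv]]
      rows <- tryCatch(
        analyze_session(s$pre$recording, s$post$recording, erp_cfg = cfg,
                        tfr_cfg = NULL, trial_types = "target"),
        error = function(e) NULL)
      if (is.null(rows)) next
      rows$subject <- sub$id
      rows$intervention <- iv
      outcomes <- rbind(outcomes, rows)
    }
  }
  res <- list(outcomes = outcomes, ledger = st$ledger)
  for (ms in measures) {
    res[[ms]] <- tryCatch(rm_anova_2x2(outcomes[outcomes$measure == ms, ]),
                          error = function(e) NULL)
  }
  res
}

# Interaction contrast estimate (actual minus sham pre-to-post change) for
# one measure from a long outcome table.
interaction_estimate <- function(outcomes, measure) {
  x <- outcomes[outcomes$measure == measure, ]
  d <- function(iv) {
    pre <- x[x$intervention == iv & x$block == "pre", ]
    post <- x[x$intervention == iv & x$block == "post", ]
    stats::setNames(post$value[match(pre$subject, post$subject)] - pre$value,
                    pre$subject)
  }
  da <- d("actual"); ds <- d("sham")
  common <- intersect(names(da), names(ds))
  mean(da[common] - ds[common])
}

#' ERP effect-recovery study
#'
#' Replicated crossover simulations with a +`delta` microvolt actual-only
#' P300 mean-amplitude change at default background noise; each study is
#' analyzed end-to-end through the offline ERP stage and the interaction
#' contrast (actual minus sham pre-to-post change) is estimated. The median
#' estimate across studies is the recovery check against `delta`. The
#' injected change is identical for every subject (the between-subject
#' effect-variability used elsewhere is zeroed here): the experiment
#' measures the pipeline's calibration against a known truth, so population
#' spread in the truth would only blur the comparison.
#'
#' @param n_studies replicate studies.
#' @param n_subjects subjects per study.
#' @param delta injected actual-only P300 change, microvolts (window-mean).
#' @param seed integer seed.
#' @param n_trials oddball trials per block.
#' @param channels montage (default: reduced centro-parietal subset).
#' @param sampling_rate Hz.
#' @return data.frame with one row per study (`study`, `estimate`).
#' @export
erp_recovery_sim <- function(n_studies = 20, n_subjects = 20, delta = 1,
                             seed = 1, n_trials = 120,
                             channels = reduced_montage(),
                             sampling_rate = 125) {
  eff <- effect_spec(delta_p300_actual = delta, delta_p300_sham = 0,
                     sd_delta_erp = 0, sd_delta_ero = 0)
  spec <- recording_spec(channel_labels = channels,
                         sampling_rate = sampling_rate)
  seeds <- child_seeds(seed, n_studies)
  out <- NULL
  for (r in seq_len(n_studies)) {
    res <- .run_erp_study(n_subjects, eff, seeds[r], spec, n_trials)
    out <- rbind(out, data.frame(
      study = r, estimate = interaction_estimate(res$outcomes, "p300_mean")))
  }
  out
}

#' Type-I error calibration of the end-to-end interaction test
#'
#' Replicated crossover studies under a null effect specification (identical
#' pre-to-post changes for both interventions), each run through the offline
#' ERP stage and the 2x2 repeated-measures ANOVA; returns the fraction of
#' studies whose interaction p-value falls below `alpha`.
#'
#' @param n_studies replicate studies (calibration to ±0.02 needs ~500).
#' @param n_subjects subjects per study (the analyzed sample was 19).
#' @param alpha nominal level.
#' @param seed integer seed.
#' @param n_trials oddball trials per block (scaled-down blocks permitted).
#' @param channels montage.
#' @param sampling_rate Hz.
#' @return list `rate`, `n_studies`, `pvalues`.
#' @export
type1_calibration_sim <- function(n_studies = 500, n_subjects = 19,
                                  alpha = 0.05, seed = 1, n_trials = 12,
                                  channels = c("Cz", "CPz", "Pz", "POz"),
                                  sampling_rate = 125) {
  eff <- effect_spec()   # defaults: equal deltas under both interventions
  spec <- recording_spec(channel_labels = channels,
                         sampling_rate = sampling_rate)
  seeds <- child_seeds(seed, n_studies)
  pvals <- rep(NA_real_, n_studies)
  for (r in seq_len(n_studies)) {
    res <- .run_erp_study(n_subjects, eff, seeds[r], spec, n_trials)
    a <- res$p300_mean
    if (!is.null(a)) pvals[r] <- a$p[a$effect == "interaction"]
  }
  ok <- !is.na(pvals)
  list(rate = mean(pvals[ok] < alpha), n_studies = sum(ok), pvalues = pvals)
}

#' Phase-locking verification study
#'
#' Synthesizes a tACS block at `frequency`, schedules a generated oddball
#' sequence phase-locked to its pulse stream, and reads the waveform phase at
#' every scheduled target's expected P300 peak.
#'
#' @param frequency stimulation frequency in Hz.
#' @param p300_latency_ms individual latency in ms.
#' @param n_trials trials in the sequence.
#' @param seed integer seed.
#' @param sampling_rate waveform rate in Hz.
#' @return list `phase_err_deg` (per target), `circ_sd_deg`,
#'   `max_rel_amp_err` (worst relative deviation of the waveform value at the
#'   P300 peak from the plateau maximum), `total_wait_s`, `n_targets`.
#' @export
phase_lock_sim <- function(frequency, p300_latency_ms = 350, n_trials = 80,
                           seed = 1, sampling_rate = 500) {
  sq <- generate_sequence(n_trials = n_trials, seed = seed)
  wf <- synthesize_waveform(tacs_waveform_spec("actual", frequency),
                            sampling_rate,
                            block_duration = max(sq$onset) + 30)
  # keep the sequence inside the plateau so every target has a pulse
  sq$onset <- sq$onset + wf$plateau[1] + 5
  sched <- schedule_phase_locked(sq, wf, list(stim_frequency = frequency,
                                              p300_latency = p300_latency_ms))
  tg <- sched$onset[sched$trial_type == "target"] + p300_latency_ms / 1000
  phase_err <- rad2deg(tacs_phase_error(tg, frequency))
  amp <- (wf$spec$intensity / 2) * sin(2 * pi * frequency * tg)
  plateau_max <- wf$spec$intensity / 2
  list(phase_err_deg = phase_err,
       circ_sd_deg = rad2deg(circ_sd(deg2rad(phase_err))),
       max_rel_amp_err = max(abs(amp - plateau_max) / plateau_max),
       total_wait_s = attr(sched, "total_wait"),
       n_targets = length(tg))
}
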