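# Oddball sequence generation, tACS waveform synthesis with pulse stream, and
# the phase-locked target scheduling used during the intervention block.

#' Generate a visual oddball stimulus sequence
#'
#' Exact-count target allocation (the design fixes 100 of 400 trials as
#' targets), uniformly shuffled, with inter-stimulus intervals drawn uniformly
#' from `isi_range`. Stimuli last `stim_duration` seconds, so successive
#' onsets are `stim_duration + ISI` apart. The frequent standard stimulus is
#' tilted to `standard_side`; targets take the opposite tilt.
#'
#' @param n_trials number of trials (default 400).
#' @param p_target target fraction (default 0.25); `n_trials * p_target` must
#'   be an integer (the design is exact-count).
#' @param isi_range `c(min, max)` ISI in seconds (default `c(1, 2.5)`).
#' @param standard_side `"left"` or `"right"` tilt for standards.
#' @param seed integer seed.
#' @param stim_duration stimulus duration in seconds (default 0.5).
#' @param first_onset onset of the first trial in seconds (default 2).
#' @return a `stimulus_sequence`: data.frame (`onset`, `trial_type`, `tilt`)
#'   with attributes `isi_range`, `standard_side`, `stim_duration`.
#' @export
generate_sequence <- function(n_trials = 400, p_target = 0.25,
                              isi_range = c(1, 2.5),
                              standard_side = c("left", "right"),
                              seed = 1, stim_duration = 0.5,
                              first_onset = 2) {
  standard_side <- match.arg(standard_side)
  assert_that(p_target > 0 && p_target < 1, "p_target must lie in (0, 1)")
  assert_that(isi_range[1] <= isi_range[2], "isi_range must be ordered")
  n_target <- n_trials * p_target
  assert_that(abs(n_target - round(n_target)) < 1e-9,
              "n_trials * p_target must be an integer (exact-count design)")
  n_target <- as.integer(round(n_target))

  with_seed(seed, {
    types <- sample(rep(c("target", "standard"),
                        c(n_target, n_trials - n_target)))
    isi <- stats::runif(n_trials - 1, isi_range[1], isi_range[2])
    onsets <- first_onset + c(0, cumsum(stim_duration + isi))
    target_side <- if (standard_side == "left") "right" else "left"
    seq_df <- data.frame(onset = onsets, trial_type = types,
                         tilt = ifelse(types == "target", target_side,
                                       standard_side),
                         stringsAsFactors = FALSE)
    structure(seq_df, class = c("stimulus_sequence", "data.frame"),
              isi_range = isi_range, standard_side = standard_side,
              stim_duration = stim_duration)
  })
}

#' tACS waveform specification
#'
#' Actual stimulation runs for the whole intervention block (about 20 min) at
#' the individual frequency; sham fades in, holds a 10 s plateau, and fades
#' out again, mimicking skin sensation with 30 s of current in total.
#'
#' @param mode `"actual"` or `"sham"`.
#' @param frequency stimulation frequency in Hz.
#' @param intensity peak-to-peak amplitude in mA (default 1).
#' @param fade_duration linear fade-in/out duration in seconds (default 10).
#' @param total_duration waveform support in seconds; defaults to 1200 for
#'   actual and `2 * fade_duration + 10` (= 30 s) for sham.
#' @export
tacs_waveform_spec <- function(mode = c("actual", "sham"), frequency,
                               intensity = 1, fade_duration = 10,
                               total_duration = NULL) {
  mode <- match.arg(mode)
  assert_that(is_scalar_num(frequency) && frequency > 0, "frequency must be > 0")
  assert_that(intensity > 0, "intensity must be > 0")
  total_duration <- total_duration %||%
    if (mode == "actual") 1200 else 2 * fade_duration + 10
  if (mode == "sham") {
    assert_that(abs(total_duration - (2 * fade_duration + 10)) < 1e-9,
                "sham support must equal 2 * fade_duration + 10 s")
  }
  structure(list(mode = mode, frequency = frequency, intensity = intensity,
                 fade_duration = fade_duration,
                 total_duration = total_duration),
            class = "tacs_waveform_spec")
}

#' Synthesize the tACS waveform and its pulse stream
#'
#' The stimulator emits a marker pulse at every ascending zero crossing of the
#' sinusoid; pulses are reported for the plateau only (zero-crossing timing is
#' reliable only at full amplitude).
#'
#' @param spec a [tacs_waveform_spec()].
#' @param sampling_rate waveform sampling rate in Hz; must be at least
#'   `4 * frequency` so peaks are resolvable.
#' @param block_duration optional block length in seconds; the returned
#'   waveform is zero-padded to it (sham stimulation stops after 30 s while
#'   the block continues).
#' @return list with `t` (s), `waveform` (mA), `pulse_times` (s),
#'   `plateau` (`c(start, end)` s), and `spec`.
#' @export
synthesize_waveform <- function(spec, sampling_rate = 500,
                                block_duration = NULL) {
  f <- spec$frequency
  assert_that(sampling_rate >= 4 * f,
              "sampling_rate below 4x frequency: peak timing unresolvable")
  dur <- max(spec$total_duration, block_duration %||% 0)
  t <- seq(0, dur, by = 1 / sampling_rate)
  amp <- spec$intensity / 2              # peak-to-peak -> zero-to-peak

  fade <- spec$fade_duration
  support_end <- spec$total_duration
  plateau <- c(fade, support_end - fade)
  env <- numeric(length(t))
  inside <- t <= support_end
  env[inside] <- pmin(1, pmin(t[inside] / fade, (support_end - t[inside]) / fade))
  env <- pmax(env, 0)

  waveform <- amp * env * sin(2 * pi * f * t)

  k <- seq(ceiling(plateau[1] * f), floor(plateau[2] * f))
  pulse_times <- k / f
  pulse_times <- pulse_times[pulse_times >= plateau[1] &
                             pulse_times <= plateau[2]]

  list(t = t, waveform = waveform, pulse_times = pulse_times,
       plateau = plateau, spec = spec, sampling_rate = sampling_rate)
}

#' Delay that lands the P300 on the next positive tACS peak
#'
#' Given a stimulator pulse at an ascending zero crossing, the sinusoid peaks
#' `T/4 + k T` later (period `T = 1/stim_frequency`). The stimulus must be
#' delayed by the smallest `d >= min_lead` such that `d + p300_latency - T/4`
#' is an integer multiple of `T`, so that the P300 elicited `p300_latency`
#' seconds after stimulus onset coincides with a positive peak.
#'
#' @param pulse_time pulse time in seconds (phase reference).
#' @param stim_frequency individual stimulation frequency in Hz (1-8).
#' @param p300_latency individual P300 latency in seconds.
#' @param min_lead minimum delay in seconds (fixation-point floor, default 0.2).
#' @return the onset delay in seconds, measured from `pulse_time`.
#' @export
compute_target_delay <- function(pulse_time, stim_frequency, p300_latency,
                                 min_lead = 0.2) {
  assert_that(stim_frequency >= 1 && stim_frequency <= 8,
              "stim_frequency must lie in [1, 8] Hz")
  assert_that(min_lead >= 0, "min_lead must be >= 0")
  T <- 1 / stim_frequency
  d <- (T / 4 - p300_latency) %% T
  if (d < min_lead) d <- d + T * ceiling((min_lead - d) / T)
  d
}

#' Phase-lock target onsets to the tACS waveform
#'
#' Reproduces the intervention-block scheduling: when a target is due, the
#' presentation waits (fixation point, at least `min_lead` seconds) for the
#' delay that makes the upcoming P300 coincide with a positive peak of the
#' tACS sinusoid. All later trials inherit the accumulated waiting time, so
#' ordering and ISIs are preserved; standards are never phase-gated. Sham
#' blocks apply no constraint.
#'
#' @param sequence a [generate_sequence()] result.
#' @param pulses pulse stream (`pulse_times` vector or a
#'   [synthesize_waveform()] result).
#' @param params list with `p300_latency` (ms) and `stim_frequency` (Hz), as
#'   returned by [estimate_stim_params()].
#' @param min_lead minimum per-target waiting time in seconds.
#' @param sham if `TRUE`, return the sequence unchanged.
#' @return the sequence with adjusted onsets; attribute `total_wait` records
#'   the summed waiting time.
#' @export
schedule_phase_locked <- function(sequence, pulses, params, min_lead = 0.2,
                                  sham = FALSE) {
  if (sham) {
    attr(sequence, "total_wait") <- 0
    return(sequence)
  }
  pulse_times <- if (is.list(pulses)) pulses$pulse_times else pulses
  assert_that(length(pulse_times) > 0, "empty pulse stream")
  f <- params$stim_frequency
  latency <- params$p300_latency / 1000

  onsets <- sequence$onset
  shift <- 0
  total_wait <- 0
  for (i in seq_along(onsets)) {
    due <- onsets[i] + shift
    if (sequence$trial_type[i] == "target") {
      ref_time <- due + min_lead
      p_idx <- findInterval(ref_time + 1e-12, pulse_times)
      assert_that(p_idx >= 1, "no pulse precedes target at %.2f s", due)
      p <- pulse_times[p_idx]
      d <- compute_target_delay(p, f, latency, min_lead = ref_time - p)
      new_onset <- p + d
      total_wait <- total_wait + (new_onset - due)
      shift <- shift + (new_onset - due)
      onsets[i] <- new_onset
    } else {
      onsets[i] <- due
    }
  }
  sequence$onset <- onsets
  attr(sequence, "total_wait") <- total_wait
  sequence
}

#' Phase of the tACS sinusoid at given times
#'
#' Readout oracle for the phase-lock invariant: returns the phase error (in
#' radians) relative to the positive peak (+90 degrees) of the plateau
#' sinusoid at each time.
#' @param times times in seconds.
#' @param frequency sinusoid frequency in Hz (ascending zero crossing at t = 0).
#' @export
tacs_phase_error <- function(times, frequency) {
  wrap_angle(2 * pi * frequency * times - pi / 2)
}
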