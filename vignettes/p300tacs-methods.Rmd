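---
title: "Phase-locked tACS and the P300: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locked tACS and the P300: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300tacs)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic data, the estimators in the online and offline
stages, the phase-locking arithmetic, the statistical layer, and the design
decisions taken where more than one defensible choice existed.

## The generative model

The package treats the P300 as the visible part of an event-related
oscillation (ERO): every stimulus adds to the EEG a burst

$$ s(t) = A \, \cos\!\big(2\pi f (t - L)\big)\,
   \exp\!\Big(-\frac{(t-L)^2}{2\sigma^2}\Big), \qquad \sigma = \frac{T}{4},
   \; T = \frac1f, $$

whose largest positive half-wave peaks at the latency $L$ with amplitude $A$
(`p300_amplitude`, μV at Pz). With $\sigma = T/4$ the burst spans barely
more than one cycle — a single dominant positive hump with small negative
side lobes, which is what a P300 looks like, while still carrying a definite
frequency $f$ (`ero_frequency`). Targets additionally receive a late
negative Gaussian wave centered at 800 ms (`n700_amplitude`, σ = 120 ms),
and standards receive the same burst scaled down by `target_standard_ratio`.
A per-channel topography weight vector (Gaussian in angular distance from
Pz, width 32°) spreads the components over the montage; it is a weight
vector, not a dipole model, deliberately.

Background activity is the sum of 1/f noise (spectral exponent 1, RMS 8 μV),
an amplitude-modulated 10 Hz alpha rhythm (5 μV), white sensor noise (2 μV
SD), and occasional high-amplitude transients (3 % of trials, 250 μV) so the
artifact-rejection stages have real work. Channels are spatially
independent — a known simplification: real EEG background is spatially
correlated, so common-average referencing removes more real-world noise than
it does here. Consequently, passing recovery tests demonstrate estimator
correctness and calibration under this model's assumptions, not performance
on any particular patient population.

### Effect injection in outcome units

Pre-to-post intervention effects must be *recoverable* — the estimate of an
injected +1 μV change should be 1 μV, not some pipeline-dependent fraction
of it. Two design choices make the injection's units equal the study's
outcome units (μV of window-mean amplitude at common-average-referenced Pz):

* the injected change is a zero-mean (Ricker-shaped) slow component whose
  central lobe fills the analysis window. A zero-area shape passes the
  0.5 Hz offline high-pass at unit gain, whereas a monophasic bump loses
  roughly half of its window mean to that filter;
* the generator normalizes the component by the common-average factor
  $1 - \bar w$ of its own montage (measured Pz amplitude after re-referencing
  is the channel value minus the montage mean).

The noiseless pipeline then measures an injected change at a gain of ~0.9
(the remainder is smearing of the component's edges across the half-open
window by the 6 Hz ERP low-pass). Oscillatory effects (`delta_ero_*`) are a
log₁₀ gain on the burst; because the wavelet ROI is a *total*-power measure,
its change only equals the injected gain where the burst dominates the ROI —
with a strong late slow wave or heavy background the measured change is
compressed toward zero. The ROI recovery study therefore isolates the burst
(no late wave, low background); the compression under realistic mixtures is
a property of log-total-power measures, not of this implementation.

Default effect sizes mirror the study's findings qualitatively: equal small
P300 decreases under both interventions (null interaction), a late-ERP
increase mainly under actual stimulation, a small ERO log-power decrease in
both, and omission rates worsening after either intervention (fatigue), each
with between-subject variability (`sd_delta_*`) so change scores have
realistic spread.

## Online stage

The on-site chain band-limits (0.1–40 Hz, zero-phase), detrends, epochs
targets from −2 to +5 s with a −2–0 s baseline, and drops epochs whose
kurtosis or joint log-probability z-scores exceed ±3 SD per channel or
globally — a functional analogue of the standard single-channel/global
tests. The P300 latency is the maximum of the across-epoch Pz average
within 250–450 ms (ties to the earliest sample; a flat window is flagged
low-confidence). A wider 250–600 ms window is available for late peaks.

### Estimating the individual ERO frequency

The stimulation frequency is the dominant delta/theta frequency of the
event-locked response around the latency. Two facts shape the estimator:

1. single-epoch spectra are background-dominated — ongoing delta power in a
   400 ms window is an order of magnitude above the evoked burst — so the
   estimate must come from the across-epoch (evoked) average, where
   phase-locked activity survives and ongoing activity shrinks by $1/N$;
2. a burst of ~1.3 cycles has spectral width $\sigma_f \approx 0.64 f$: its
   power spectrum has a nearly flat top, so the spectral argmax is fragile —
   residual noise tilts it by a hertz or more. The frequency information
   actually lives in the *envelope duration* (a quarter period by model).

The default backend therefore correlates the 1/f-prewhitened evoked average
against the package's burst template over a fine frequency grid (0.05 Hz)
and returns the best-matching frequency, after projecting out a late-slow-
wave nuisance shape so its tail cannot pull low-frequency templates. Plain
periodogram-argmax backends (`evoked`, `per_epoch`) are retained, with the
documented lower-frequency tie rule; the zero-padded grid keeps the
protocol's ≤0.1 Hz resolution. At the study's design sizes (50 subjects,
400-trial blocks, default noise) the median absolute errors are a few
milliseconds for the latency and well under 0.3 Hz for the frequency; the
acceptance script recomputes both.

## Phase-locked scheduling

The stimulator pulses at every ascending zero crossing, so the sinusoid
peaks $T/4 + kT$ after each pulse. For a pulse at $p$ and stimulus delay
$d$, the P300 lands on a peak iff $(d + L - T/4) \bmod T = 0$; the
scheduler takes the smallest such $d$ at least `min_lead` (default 0.2 s —
the fixation point must be perceivable; the waiting time per target is
therefore below `min_lead` $+ T$). Standards are never gated; they inherit
the accumulated waiting (cascade) so ordering and ISIs are preserved.
Onsets are continuous in seconds; reading the synthesized waveform at
`onset + latency` reproduces the plateau maximum to machine precision, which
the scheduling tests verify at the band edges (1 and 8 Hz) as well as at
random frequencies. Pulses are emitted only during the plateau: zero
crossings during amplitude ramps have no stable timing in hardware either.

## Offline stages

The offline chain merges the pre/post blocks, resamples to 250 Hz
(anti-aliased decimation), band-passes 0.5–40 Hz, detrends, optionally
excises marked segments and repairs named bad channels by spherical-spline
interpolation (stiffness 4, 50-term Legendre series). Filtering throughout
the package is zero-phase frequency-domain filtering with Butterworth
magnitude responses on an even periodic extension (5-smooth FFT lengths):
identical magnitude to a forward–backward IIR pass, exactly zero phase, and
stable at 0.1 Hz cutoffs.

The ERP branch re-references to the common average, low-passes at 6 Hz (to
exclude alpha; the time–frequency branch never sees this filter), epochs
−0.5–1.5 s with a −0.5–0 s baseline, and applies trial-by-trial rejection
with the protocol's strict inequalities: channels with within-epoch
peak-to-peak amplitude **>150 μV** are marked (the within-epoch peak-to-peak
range is the operational meaning of a per-channel amplitude threshold in
trial-by-trial cleaning); channels marked in **>15 %** of epochs are excluded
globally; epochs with **>10** marked channels are dropped; marked channels
in retained epochs are spline-interpolated, and unmarked channels are never
altered. Windows are half-open in samples; peak ties take the earliest
latency. The default P300 mean window is 200–550 ms (the 250–550 ms variant
used in some displays is a config preset).

The time–frequency branch epochs −0.5 to +1.6 s and convolves Pz with
analytic Morlet wavelets on 47 log-spaced frequencies from 0.25 to 6 Hz.
The wavelets are constant-Q with 10 cycles: on a logarithmic grid a
constant *relative* bandwidth is the natural choice, and ~10 cycles is what
concentrates a sinusoid's power into its three nearest bins. The price is
long time support at the lowest frequencies (a 0.25 Hz wavelet does not fit
a 2.1 s epoch); rather than truncating the wavelets, the cone of influence
is flagged in an edge-validity mask, and ROI means are reported both with
masked cells included (the ROI's lowest frequencies are edge-contaminated
by construction, as the original report also cautions) and excluded.
Power is log₁₀-transformed per epoch *before* averaging — the order matters
and a property test guards against silent reordering. No spectral-domain
baseline is applied; the time-domain −0.5–0 s baseline precedes the CWT.

## Behavior

Omission errors count target trials without a correct target-key response —
wrong-key presses *and* missing responses, per the definition used in the
protocol ("non-target button responses to target stimuli"); a configuration
switch restricts to key presses only, since the narrower reading is also
defensible. d′ clips hit and false-alarm rates to $[1/2N,\, 1 - 1/2N]$
before the inverse-normal transform — uncorrected extreme rates are
infinite. RT variability is the SD of correct-target RTs (the measure is
conventionally reported without a formula). The d2 test is scored per its
definitions: processing speed is the total characters processed (per line,
up to the last mark), omissions are unmarked targets within the processed
span, commissions are marked distractors, and concentration performance is
correct hits minus conducted (commission) errors. Outlier exclusion is the
single-pass 3-SD rule, strict (> 3 SD excludes; exactly 3 SD is retained),
computed per measure across the analyzed sample without re-iteration.

## Statistics

With two-level factors the 2×2 within-subject ANOVA needs no sphericity
correction, and each effect's F equals the squared paired t of its
orthogonal contrast — the implementation uses that decomposition and is
cross-checked in the tests against `stats::aov` with an error stratum.
Partial η² is $F\,df_1/(F\,df_1 + df_2)$, which reproduces every reported
(F, η²) pairing at two decimals. Cohen's d for paired data is the mean
difference over the SD of differences. Holm's step-down is implemented
directly (sorted p-values times $m, m-1, \dots$, running maximum, capped at
1) and checked against `stats::p.adjust`. Change-score correlations stack
both interventions' post-minus-pre scores (two rows per subject) and Holm
over all pairs of the measure matrix; per-intervention pooling is available.
Subjects with incomplete cells are dropped listwise per measure, mirroring
the varying per-measure sample sizes such studies report.

## Problem sizes and calibration

The replicated simulation studies are sized for a desk machine and state
their scale in the results they write:

* online recovery: 50 subjects, full 400-trial blocks at 250 Hz (mobile EEG
  systems record at 250-500 Hz and the offline stage resamples to 250 Hz
  regardless), default noise;
* ERP effect recovery: 20 replicate studies × 20 subjects, 120-trial blocks
  at 125 Hz on a 6-channel centro-parietal montage, with the injected
  change identical across subjects (the study measures pipeline
  calibration, so population spread in the truth would only blur it) — the interaction contrast is a
  per-subject difference of differences, so block length trades precision
  per study against runtime while the median across studies stays unbiased;
* type-I calibration: 500 replicate 19-subject null studies with 12-trial
  blocks on a 4-channel montage at 125 Hz. The interaction test's level
  depends on the per-subject contrasts being approximately normal, which
  holds at any block length (window means of filtered Gaussian noise plus
  normal between-subject deltas), so tiny blocks calibrate the level
  correctly at a tiny fraction of the cost.

## Known limitations

* No realistic head model: topography is a weight vector; spatially
  independent channel noise makes common-average referencing kinder than in
  real data.
* The ICA stage is a pluggable contract (any invertible decomposition plus
  a selector, e.g. correlation with a reference trace >0.7); the default
  pipeline relies on the statistical and trial-by-trial rejection stages,
  so stereotyped ocular artifacts are out of the default generator's scope.
* The generator's burst model and the matched-template frequency estimator
  share the quarter-period envelope assumption; with real data one should
  prefer the `evoked` periodogram backend for a model-agnostic first look
  and treat the matched fit as model-based refinement.
* BrainVision I/O is not implemented; interchange is classic EDF plus
  BIDS-style `events.tsv`.
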