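---
title: "Methods: state-dependent spike quantification, theta amplitude change, and the behavioral battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent spike quantification, theta amplitude change, and the behavioral battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes, and why

`epiphys` is a quantitative pipeline for a common experimental design in
mouse models of genetic epilepsy/intellectual-disability syndromes: chronic
video-EEG/LFP recordings taken **before** (Phase I) and **after** (Phase II)
an adult-initiated gene-restoration manipulation in the same animals,
together with behavioral cohorts (flurothyl seizure-threshold latencies,
remote contextual fear memory). Three kinds of quantity are produced:

1. **State-dependent interictal spike (IIS) rates.** IIS are brief
   high-amplitude paroxysmal transients between seizures; their rate indexes
   circuit hyperexcitability and, in the disease model this pipeline targets,
   is dramatically elevated in mutants during wake and further elevated
   during sleep.
2. **Within-subject theta-amplitude change.** Hippocampal theta (6–12 Hz)
   amplitude during exploration, estimated with a complex Morlet wavelet
   transform, compared across phases within each animal and tested with a
   sign-flip permutation test plus bootstrap confidence bands.
3. **The behavioral statistical battery.** Type-III two-factor ANOVA
   (Cre × genotype) with Bonferroni pairwise comparisons, mixed
   repeated-measures ANOVA, MANOVA (Pillai), unpaired/paired t, Wilcoxon
   rank-sum, Cohen's d, and the activity suppression ratio.

Because such recordings are rarely deposited, the package ships a
synthetic-data generator with retained ground truth; every analysis stage is
tested end-to-end against it.

## The synthetic world

`simulate_recording()` produces four channels at a configurable rate
(default 2 kHz; tests use 250 Hz, which still satisfies Nyquist for the
1–100 Hz analysis range):

- **hLFP**: 1/f^a background (spectrally shaped white noise, default a = 1,
  RMS fixed at 0.1 mV), a theta sinusoid at 8 Hz and a delta sinusoid at
  2.5 Hz (band centers; the parameter set deliberately exposes amplitudes
  only, since the analyses are band-level), plus inserted spikes.
- **Spikes**: Poisson within each vigilance state at that state's rate,
  inserted as biphasic transients — a positive Gaussian-windowed peak
  (width `spike_width_ms`) followed by a slow negative after-wave — because
  a positive-threshold detector must be exercised by peak-positive events.
  Spikes appear on all EEG/LFP channels (full amplitude on hLFP, attenuated
  on cortical EEG), emulating events that generalize across channels.
- **States**: alternating exponential-duration wake/sleep bouts; the wake
  bout mean is set from `sleep_fraction` and `sleep_bout_s` so the expected
  sleep fraction matches the request.
- **EMG**: white noise whose RMS switches abruptly between `emg_wake_rms`
  and `emg_sleep_rms` at state boundaries.

All randomness flows from one seed through per-component sub-streams;
identical seed + parameters give bit-identical output.

**Default rates are a stated world, not measurements.** The disease model
fixes only fold relations (mutant wake IIS ≈ 50× wild-type; mutant sleep ≈
18× mutant wake). Absolute rates are free parameters; the defaults (mutant
wake 0.5/min, mutant sleep 9/min, wild-type wake 0.01/min) were chosen once
as plausible for a strongly epileptic model and are not tuned thereafter.
Recovery tests that need estimable wild-type rates state their own rates
explicitly (e.g. 0.4/min over 20-min sessions) so that expected counts stay
in a regime where a 25% tolerance is meaningful.

**What a green test does not establish.** The generator has no electrographic
seizures, spindles, ripples, realistic EMG spectra, movement artifacts other
than the synthetic ones injected by tests, or non-sinusoidal theta; passing
tests certify the estimators against the stated statistical structure, not
against biological waveform diversity.

## Sleep/wake segmentation

Sleep is inferred from an abrupt quieting of the EMG. `segment_states()`
computes a sliding-window RMS (default 1 s), compares it to
`quiet_ratio` (default 0.5) times a wake-reference RMS, and requires
candidate sleep bouts to last at least `min_bout_s` (default 10 s) — the
conventional scales of rodent sleep scoring. An optional per-sample
immobility series vetoes sleep during movement, standing in for video
confirmation.

**Wake reference.** An early design used the median windowed RMS. That fails
as soon as a recording is more than half asleep — the median then *is* the
sleep level and no quieting is ever detected — which exponential bout
statistics produce regularly at a 0.5 sleep fraction. The reference is
therefore the 90th-percentile windowed RMS (`ref_quantile = 0.9`): an
estimate of the wake level that survives sleep-heavy recordings, at the cost
of requiring at least ~10% of the recording to be awake. The exact criterion
used by human scorers in the source workflow is unrecoverable; this
thresholded-RMS rule is a stated stand-in, and lowering `quiet_ratio` never
increases total sleep time (tested property).

## Spike detection and artifact rejection

`detect_spikes()` logs one event per contiguous excursion of the hLFP above
`threshold_mV` (default +1 mV, the field's convention for high-amplitude IIS
in a CA1 depth channel), at the excursion's maximum. Excursions separated by
less than `refractory_s` (default 0.2 s; a merge rule must exist because IIS
are multiphasic, and no published value is available) merge into one event
at the larger peak. The detector is verified sample-for-sample against an
exhaustive reference scan and is monotone in threshold.

`reject_artifacts()` implements the qualitative field criterion —
"unusually high amplitude with time-locked peaks on several channels" — as a
conjunction: an event is flagged (never deleted) only if at least
`sync_min_channels` (default 2) other channels co-peak within
`sync_window_s` (default 10 ms) **and** the hLFP peak exceeds `amp_cap_mV`
(default 10 mV). Both are required so that genuine generalized spikes, which
are synchronous but of physiological amplitude, survive. Shape-based
rejection is intentionally not implemented: no operational definition of
"atypical shape" exists to implement, and guessing one would be worse than
documenting the limitation.

Rates divide accepted-event counts by state time (events/min); a state with
zero time yields an explicit `NA` flagged undefined rather than a silent
zero. Fold changes are ratios of group mean rates, with a configurable
pseudo-rate substituted (and annotated) for a zero denominator.

## Morlet amplitude and the theta/delta ratio

`morlet_amplitude()` evaluates 50 log-spaced frequencies on [1, 100] Hz with
complex Morlet wavelets of six periods (`sigma_t = n_cycles / (2 pi f)`).

- **Normalization.** "Unit area" is implemented as unit L1 norm of the
  magnitude envelope (continuous normalization `1/(sigma_t sqrt(2 pi))`,
  discretized). A unit-amplitude sinusoid then reads ~0.5 at its own
  frequency at *any* frequency, which is what makes amplitudes comparable
  across the log grid. Unit-energy (L2) normalization is available by flag
  for users who prefer power-preserving conventions.
- **Edges.** Convolution uses reflect padding; samples within one truncated
  half-support (4 sigma_t) of either boundary are recorded per frequency and
  excluded from all time averages. The choice is conservative and matters
  mainly below ~2 Hz on short test traces.
- **Oracle.** The implementation is tested against the closed-form response
  of a unit-area Morlet to a sinusoid,
  `0.5 exp(-sigma_t^2 (2 pi (f - f0))^2 / 2)`, to within 2% wherever the
  response exceeds 5% of its peak, and for homogeneity under trace scaling.

`theta_delta_ratio()` takes mean squared amplitude over the band rows
(theta 6–12, delta 1–4 Hz), divides, and smooths with a centered 1-s moving
average. Samples with zero delta power are flagged infinite and excluded
from `select_representative_window()`, which returns the 1-s window with the
highest mean ratio, earliest-start on ties.

## Phase change, bootstrap, permutation

For each animal, a phase's amplitude is the per-frequency time average over
reliable samples of the first-10-minute window of each session, averaged
across the phase's sessions (three per phase in the emulated design). The
normalized change is `(phase2 - phase1) / phase1`. Whether movement periods
should be isolated before averaging is genuinely open in the source
workflow; we time-average over the whole window and note that a
movement-conditioned variant would require the immobility series.

The 95% confidence band resamples **animals** (the exchangeable unit) with
replacement, 2000 times by default (the level, not the replicate count, is
externally fixed), percentile intervals per frequency. The permutation test
statistic is the animal-mean of band-averaged change; the null exchanges
each animal's phase labels independently, i.e. a sign flip — the natural
exchangeable null for a within-subject change. With n animals and
`2^n <= n_shuffles` the test enumerates all sign patterns exactly (and the
suite checks it against direct enumeration); otherwise it samples with the
add-one correction `p = (1 + #{|null| >= |obs|}) / (n_shuffles + 1)`.
Two-sided throughout.

## Behavioral statistics

- **Type-III two-factor ANOVA** via `drop1()` on a sum-to-zero-contrast
  `lm`, because the cohorts are unbalanced and the field's standard software
  reports type III. For balanced designs this provably coincides with
  sequential SS (tested).
- **Mixed RM ANOVA** as the classical univariate `aov` with
  `Error(subject/within)` strata; cross-checked algebraically against a
  two-factor ANOVA on subject-mean-centered data (within terms) and a
  one-way ANOVA on subject means (between term). Sums of squares below
  `1e-10` of the total are reported as F = 0, p = 1 rather than as ratios of
  rounding noise.
- **MANOVA** reports Pillai's trace per term. A rank-deficient residual
  covariance (e.g. duplicated endpoints) triggers pivoted-QR column
  dropping with a warning, so the fully degenerate case collapses to the
  univariate ANOVA instead of erroring.
- **Wilcoxon W convention**: the Mann–Whitney U of the first-listed group
  (R's convention), with the classical rank sum available by flag; the
  literature this targets does not say which it reports, so the convention
  is explicit and configurable. Exact p for small samples without ties,
  verified against full rank enumeration.
- **Cohen's d** is the pooled-SD standardized mean difference reported as a
  magnitude, matching reporting practice where both directions of effect
  get positive d.
- **Activity suppression ratio** `test / (train + test)` over matched
  0–2 min windows; 0.5 = no suppression. Chosen over freezing because it is
  robust to genotype differences in baseline twitching during freezing
  bouts.
- Latency stage names are fixed as `clonus`, `tc`, `the` (first myoclonic
  jerk, generalized tonic/clonic, total hind-limb extension).

Degrees of freedom are always reported as computed from the data actually
analyzed; published legends occasionally carry internally inconsistent dfs,
and this package does not force printed values.

## Numerical and scaling choices

- Tests and simulations run at fs = 250 Hz and minutes-long sessions purely
  for CPU budget; all laws under test (Poisson counts, band responses,
  F distributions) are fs-independent above Nyquist, and production defaults
  remain 2 kHz.
- Monte-Carlo calibration checks (type-I error ≈ 5%) use 400–500 seeds with
  3-SE binomial bands; estimator-recovery checks state their tolerance in
  the units of the quantity (3 SE for counts, 25% for fold changes, 2% for
  the wavelet response).
- Zero-variance inputs (constant cells, identical within-levels) are mapped
  to explicit F = 0 / p = 1 results, and undefined quantities (zero-time
  states, zero pooled SD, both-zero activities) surface as flagged `NA`s,
  never silent zeros.

## Known limitations

- Real figure-level statistics require the original per-figure source data,
  which the user must supply as `cohort_table()` CSVs; none ship with the
  package.
- No REM/NREM substaging, no spectral sleep scoring, no seizure detection,
  no spike-shape classification, no phase–amplitude coupling.
- The EMG rule needs at least ~10% wake to anchor its reference quantile.
- The generator's theta/delta components are fixed-frequency sinusoids;
  analyses sensitive to within-band frequency drift are not exercised by it.
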