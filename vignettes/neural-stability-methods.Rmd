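---
title: "Quantifying auditory brainstem neural stability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying auditory brainstem neural stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abrstab)
```

## The measurement model

The quantity this package computes is the *neural stability* of an auditory
brainstem response: the Pearson correlation between two independently
averaged response waveforms obtained from the same recording session.  If
every trial evoked the same response, the two averages would differ only by
residual recording noise and the correlation would approach 1; trial-by-trial
fluctuation of the underlying response (latency jitter, amplitude
variability, intermittent desynchronization) pushes it toward 0.

The two averages are not arbitrary halves.  Speech stimuli are presented in
alternating polarity and recorded on two channels (one per ear), so a naive
split could correlate polarity-locked artifacts — the cochlear microphonic
and stimulus leakage flip sign with polarity — or channel and
collection-order effects, instead of neural repeatability.
`buildSubaverages()` therefore pairs condensation sweeps from channel A with
rarefaction sweeps from channel B and vice versa.  Each subaverage then
contains equal numbers of both polarities and both channels, the two draw on
disjoint trial sets, and any sign-flipping component cancels *exactly* in
the mean (the cancellation is algebraic, not statistical; the package tests
it to machine precision and reports it as an attenuation in dB under noise).
Clicks are recorded with a single polarity, so the same crossed scheme is
applied with the first/second halves of the accepted sweeps (collection
order) standing in for the polarity split; this preserves disjointness and
channel balance, and is exposed as `splitByCollection()`.

Correlations are computed over component windows (`componentWindows()`):
click 1–8 ms, and for the 40 ms /da/ response the full response 0–55 ms,
onset 5–10 ms, FFR (sustained) 22–40 ms, and offset 45–50 ms.  Windows are
half-open `[start, end)` with a centralized floor-based ms-to-index rule
(`msToIndex()`), so adjacent windows never share samples and window lengths
are exact (e.g. 1100 samples for 0–55 ms at 20 kHz).  Correlations are
Fisher-transformed (`fisherZ()`) before modeling; because noiseless
simulations legitimately reach r = 1, the transform clamps |r| at 1 − 1e−7
instead of erroring, while a *constant* windowed waveform (undefined
correlation) is always a hard error.

### Expected stability under additive noise

For templates corrupted by additive noise of per-sweep variance σ² that is
independent across sweeps, the subaverage of n sweeps carries noise variance
σ²/n and the expected correlation over a window with template variance V_s
is approximately

E[r] ≈ V_s / (V_s + σ²/n).

This closed form is the package's primary quantitative oracle: the
acceptance suite simulates 200 independent recordings at n = 3000 sweeps per
subaverage and requires the Monte-Carlo mean to match the prediction within
0.02.  Band-limited (rather than white) noise leaves the expectation intact
— the sample variance still estimates the marginal noise variance — but
inflates the variance of individual r values because fewer effectively
independent samples fall in a window; the short 5 ms onset/offset windows
are noticeably noisier estimators for exactly this reason.

## The synthetic generator

`makeTemplate()` builds deterministic response templates: a click epoch of
−5 to +20 ms containing Gaussian-shaped waves I/III/V (1.7/3.9/5.7 ms), and
a /da/ epoch of −5 to +55 ms containing a V/A onset complex (6.6/7.5 ms), a
transition trough C (18.5 ms), a sustained portion whose carrier is locked
to the fundamental (default f0 = 100 Hz) with an attenuated second harmonic,
and an offset wave O near 48 ms.  The sustained troughs D, E, F sit exactly
one fundamental period apart (10 ms at 100 Hz) — the interpeak interval
equals the wavelength of f0, as it does physiologically.  Peak latencies and
amplitudes are literature-typical constants, exposed through the `peaks`
argument; no published values exist for this exact protocol, so they are
package defaults, not estimates.  The /da/ fundamental is held constant at
100 Hz: natural /da/ tokens ramp their f0, and this simplification is
deliberate (the spectral detector uses nearest-bin logic, so a constant f0
keeps its calibration transparent).  A consequence worth noting: 100 Hz sits
directly on the 100–3000 Hz analysis band edge, where the bandpass gain is
−3 dB per pass — true of the real recording chain as well — so refiltering
attenuates the FFR slightly, and the filtering-idempotence contract is
stated for mid-band content.

`simulateSweeps()` perturbs a template per trial: latency jitter
(N(0, jitterSd²), applied by linear-interpolation resampling — band-limited
shifting is unnecessary at these SNRs), a multiplicative amplitude factor
(CV `ampCv`), additive Gaussian noise band-limited to 100–3000 Hz and
rescaled to an exact marginal SD, occasional 105 µV artifact transients
(`artifactRate`), and a deterministic 1000 Hz post-onset sinusoid whose sign
follows stimulus polarity (`polarityComponentAmp`), the stand-in for
cochlear-microphonic/stimulus artifact that the balanced subaveraging must
cancel.  The noise is filtered in a single pass: for stationary noise only
the magnitude response matters, and one pass halves the cost of the
zero-phase filter used on signal paths.

`simulateCohort()` generates trait and stability tables from exactly the
random-intercept model the inference targets: Zr_ij = µ + α_j + β·AQ_i +
b_i + e_ij, with sum-to-zero component offsets.  The defaults are the study
conditions the package models: 40 participants; AQ mean 21.56, SD 12.53
(integer, clamped to 0–50, split into five capped subscales); µ = 0.43;
offsets full −0.38, onset +0.24, FFR −0.15, offset −0.47, click +0.76
(the implied fifth level); β = −0.023 Zr per AQ point.  The two variance
components are not published; participantSd = 0.54 and residualSd = 0.64
are back-solved so that the fixed effects account for ≈29% and fixed plus
random for ≈58% of total variance at those fixed-effect magnitudes — the
reported variance-decomposition targets.  SRS-2 T-scores are generated with
a 0.88 correlation to AQ, ages uniform over 6–16.9 years, VCI normal
(109, 14.4); the `group` label uses the conventional AQ ≥ 32 cut.

What the generator does *not* emulate: nonstationary EEG background (alpha
bursts, movement), myogenic artifact structure, electrode drift, the f0
trajectory and formant structure of a natural Klatt /da/, adaptation across
the session, or cochlear-microphonic physiology (the polarity component is
a fixed sinusoid).  Passing tests therefore demonstrate that the *pipeline*
is correct and calibrated under its stated noise model, not that any
particular empirical effect size will replicate in children.

## Preprocessing parameters

* `filter.low_hz = 100`, `filter.high_hz = 3000` (Hz): the conventional
  brainstem band, realized as a 4th-order Butterworth applied
  forward–backward (`signal::filtfilt`), which preserves latencies.  Each
  sweep's mean is removed first; an IIR start-up transient from a DC offset
  would otherwise dwarf sub-microvolt responses on a short epoch.
* `reject.threshold_uv = 35` (µV): a sweep is rejected when its peak
  magnitude *strictly exceeds* the threshold — a sweep peaking at exactly
  35.0 µV is kept.  Rejection is per-sweep, hence order-independent, and by
  default is evaluated on filtered sweeps (`reject_on = "filtered"`),
  matching acquisition systems that filter before averaging.
* `accumulate.target = 1500` sweeps per (channel × polarity) buffer: the
  low-noise criterion; the first 1500 accepted sweeps are kept in arrival
  order and a shortfall is an error that reports the deficit.

## Response detection and noise metrics

`spectralFTest()` decides whether the sustained response exceeds the noise
floor.  The Hann-windowed, demeaned 22–40 ms segment is evaluated at the
frequency nearest f0 on a fine grid (the zero-padding-equivalent grid,
rate/4096), and compared against 2K flanking frequencies.  With an 18 ms
segment the intrinsic (Rayleigh) resolution is rate/n ≈ 55.6 Hz, and
periodogram values closer than about two Rayleigh steps are strongly
correlated under a Hann taper; the noise bins are therefore placed at
±2j·Rayleigh offsets (j = 1..K) from the signal — at least two steps from
the signal *and* from each other — borrowing from the upper side where the
lower side would cross DC or the band edge.  Under the null each bin's
power is then an effectively independent χ²₂ variate and F = P_signal /
mean(P_noise) follows F(2, 4K).  Defaults K = 5 and α = 0.05 are
conventional steady-state-response detection settings; the empirical type-I
rate over thousands of white-noise replicates sits at ≈0.05 (the acceptance
suite requires [0.03, 0.07] at 1000 replicates).  Click-response presence is
*not* decided algorithmically — in practice it is established by expert
visual inspection — so the pipeline accepts an external presence flag per
participant rather than pretending to automate that judgment.

`prestimWindow()` encodes the 10%-of-analysis-span rule for the prestimulus
noise interval, with the protocol's fixed values as defaults: 0.8 ms for the
click (10% of the 8 ms span) and 5 ms for the /da/ response.  The stated
5 ms is kept as the default even though a literal 10% of the 55 ms span
would give 5.5 ms; the rule remains available as the generic helper.
`prestimRms()` is the RMS over −prestim ≤ t < 0 and is blind to
post-stimulus content by construction.

## The inferential chain

Models M0–M3 (`fitStabilityLmm()`, `fitModelSet()`) are fit with
`lme4`/`lmerTest` by **maximum likelihood, never REML**, because BIC model
selection and likelihood-ratio tests require comparable likelihoods.  The
component factor is sum-coded with the click level omitted, so the reported
estimates are deviations from the grand mean and the implied click deviation
is minus their sum; `componentEffects` always carries all five and their sum
is zero to machine precision.  t-tests use Satterthwaite degrees of freedom
(via `lmerTest`); 95% CIs are Wald intervals on those df.  Convergence
messages are surfaced as a `converged` flag, never swallowed.

`fitModelSet()` subsets once to the observations complete for the richest
model's covariates so that all BICs are computed on identical data;
`selectModel()` refuses fits on differing observation sets.  This is a
deliberate tightening: with missingness, per-model samples would otherwise
drift and BIC differences would be meaningless.  Missing components per
participant are simply absent rows; no imputation or listwise deletion
across components is applied (`validateTraits()` preserves missingness and
flags per-trait availability instead).

Marginal and conditional R² follow the Nakagawa–Schielzeth variance
partition — var(Xβ̂) over var(Xβ̂) + Σvar(random) + σ² for the marginal,
adding the random-intercept variance to the numerator for the conditional —
implemented directly (≈10 lines for a random-intercept model) and verified
in tests against a plug-in variance oracle computed from the generator's
known components.  `deltaR2()` is the marginal-R² difference of nested fits
on identical observations.  Pairwise component contrasts use `emmeans` with
the studentized-range (Tukey) adjustment on Satterthwaite df; with two
groups the adjustment provably reduces to the plain t-test, which is tested
to 1e−6.  AQ-subscale contributions are tested by likelihood ratio
(`aqSubscaleLrt()`): reduced model component + (AQ − subscale), full model
adding the subscale, χ² = 2ΔlogLik on 1 df.  Note the proper null for
calibrating this test has *no* trait effect at all: if the total-AQ effect
is active, the subscale genuinely carries signal through the total and the
statistic is non-central.

`rmanovaGG()` (backed by `car::Anova` on a multivariate linear model)
reports within-subject F tests with Mauchly's sphericity test (converted to
the standard χ² approximation) and the Greenhouse–Geisser ε, applying the
correction when Mauchly rejects at 0.05.  Two-level factors satisfy
sphericity trivially and are reported with ε = 1 exactly; ε is bounded below
by 1/(k−1).  `designVif()` computes VIF_j = 1/(1 − R²_j) from regressing
each predictor on the rest, with exact collinearity reported as Inf;
`welchT()` and `corrTest()` wrap the base unequal-variance t-test and
Pearson test for the preliminary screens.

## Numerical and reproducibility choices

* Seeds are mandatory for cohorts and default to 0 elsewhere; every
  simulation call runs under its own seed without disturbing the caller's
  RNG state.  After seeding, 64 draws are discarded: generator states seeded
  from nearby integers share structure in their first outputs, and
  simulation batches routinely use consecutive seeds — without the warm-up,
  batch summaries (e.g. CI coverage across replicate cohorts) can be
  visibly overdispersed.
* The sweep store is an open two-file format (headerless CSV matrix + JSON
  sidecar, format version `abrstab-1`, amplitudes in µV, times in ms);
  `readSweeps()` validates field presence, units, and the
  n_samples = round(window_ms × rate/1000) consistency rule.  Vendor binary
  formats are out of scope.
* Unequal buffer sizes are a hard error by default (the acquisition design
  guarantees equality); truncation to the common minimum is available but
  must be requested.
* Waveform exports round to 6 significant digits, sufficient for re-reads
  to agree within 1e−5 µV at physiological amplitudes.

## Problem sizes

The test suite exercises full-scale buffers (1500 sweeps) where counts
matter, and reduced sizes elsewhere: the Monte-Carlo attenuation check runs
200 replicates at n = 3000 sweeps per subaverage on the 25 ms click epoch;
detector calibration uses 1000 white-noise replicates; parameter recovery
uses 100 cohorts of 200 participants; BIC-consistency, contrast-calibration
and LRT simulations use 40–150 replicates of 40–100-participant cohorts.
The end-to-end pipeline test uses 6 participants at 40 sweeps per buffer;
`runPipeline()` defaults (20 participants, 1500 sweeps per buffer) complete
in a few minutes on one core.

## Known limitations

* An 18 ms FFR segment gives ≈56 Hz intrinsic resolution, so the spectral
  detector tests a single bin at f0 against ~±1 kHz of flanking spectrum;
  harmonic-sum and Hotelling-T² variants are out of scope.
* The stability statistic assumes the two subaverages share a timebase
  exactly; resampling or cross-recording comparisons are not supported.
* Repeated-measures ANOVA follows standard within-subject df algebra;
  published dfs from other software occasionally disagree with that
  algebra, and this package makes no attempt to reproduce nonstandard
  conventions.
* Peak picking (latencies/amplitudes of waves I–V) is deliberately absent:
  stability is a whole-waveform statistic and the package does not score
  individual waves.
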