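---
title: "Quantile-spectral analysis of nanomotion recordings for drug susceptibility testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-spectral analysis of nanomotion recordings for drug susceptibility testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodst)
```

## The measurement and the analysis problem

Living cells attached to a micro-fabricated cantilever transfer part of
their metabolic and cytoskeletal activity to the sensor as sub-nanometer
deflections ("nanomotion"). A recording is a single-channel deflection time
series sampled at tens of kilohertz, annotated with three phases: a short
*blank* phase (bare sensor), a *medium* phase (cells, no drug) and a *drug*
phase after compound addition. The analysis task of this package is
phenotypic drug susceptibility testing (DST): decide, from the signal
alone, whether the attached cells respond to the drug — treated versus
untreated, or drug-susceptible versus drug-resistant.

Two conventions run through everything downstream:

* **Recording clock.** t = 0 is the start of the medium phase. Drug-onset
  intervals such as "120–130 min" are stated on this clock; the blank
  phase sits at negative times and never enters feature intervals. The
  blank duration is instrument-dependent and left configurable.
* **Arbitrary deflection units.** The optical readout is uncalibrated, so
  every decision-relevant statistic is either scale-invariant (spikiness,
  Jensen–Shannon distance, quantile ratios, interval ratios) or made
  comparable by z-scoring on the training set before classification.

## The quantile spectrogram

Welch's method estimates a power spectral density (PSD) by averaging
periodograms of overlapping, tapered segments. Averaging throws away the
distribution of power across segments, which is exactly where intermittent
cellular activity lives. The core transform here keeps that distribution:
for each analysis window (default 5 min; 15 min for the longer-exposure
protocol) the signal is cut into Welch segments, each segment yields a
one-sided PSD-normalized periodogram, and at every frequency bin the
empirical *quantiles* across segments are taken at levels 0.1–0.9. Stacked
over successive windows this gives a 3-D array: quantile level × frequency
× time.

Numerical choices, all configurable and all fixed by defaults for
determinism:

* Segment length 1 s (1 Hz resolution — sufficient for the 0–10 Hz band
  where treated/untreated contrast was reported), 50% overlap, periodic
  Hann taper, per-segment constant detrend. A 5-min window then holds
  several hundred segments, enough for stable deciles.
* Quantiles use the linear-interpolation order-statistic estimator
  (type 7), which is deterministic and monotone in the level by
  construction.
* Overlapping segments are correlated; quantiles are nevertheless computed
  over the raw segment set. This biases quantile *variance*, not location,
  and keeps the estimator pinned to a verifiable baseline: the mean over
  segment periodograms equals the textbook Welch estimate exactly (tested
  against an independent implementation at 1e-10 relative).
* The DC bin is excluded from every band after constant detrend; trailing
  partial windows and segments are dropped everywhere.

For Gaussian noise, periodogram ordinates follow a scaled chi-squared law
with 2 degrees of freedom (an exponential), so closed forms exist for every
quantile curve; the tests use those as oracles, including the
median-to-mean ratio ln 2.

## From spectrogram to features

A *feature descriptor* names one scalar: a per-window band statistic,
pooled over the windows of a half-open clock interval and reduced to a
percentile, optionally compared (difference or ratio) with a second
interval. The per-window statistics are:

* `band_power` — mean PSD over the band's bins at one quantile level;
* `spikiness` — max/median over band bins: scale-free peakedness. The
  source protocol names this quantity but never defines it; max/median is
  a declared convention, isolated behind the descriptor kind so a crest
  factor or max/mean variant is a one-point change;
* `js_chi2` — Jensen–Shannon distance (base-2 logs, square root, a metric
  in [0, 1]) between the band's values and a mean-matched chi-squared
  reference, discretized into 16 equal-probability bins. Default reference
  df = 2, the raw Gaussian-periodogram law; configurable because
  quantile-spectrum values are order statistics rather than raw ordinates.
  Which distribution is compared to the reference is ambiguous in the
  protocol; per-window band values at a fixed level is the declared
  choice;
* `quantile_ratio` / `quantile_difference` — mean band power at one level
  against another.

Two further declared readings of ambiguous phrasing: the summary
percentile pools per-window values *over windows* (not over bins or
levels), and a phrase like "during the 120–130 and 210–220 min intervals"
is read as two interval summaries plus their difference/ratio in the
grammar. The full Cartesian grammar (kinds × bands × levels × intervals ×
percentiles × combinators) is combinatorially large — the original
protocol reports hundreds of thousands of features — but the default grids
emit a few hundred columns, which desk-scale cohorts can support. Every
feature is reproducible from the spectrogram plus its canonical name
string; assembly refuses non-finite values rather than imputing.

## Classification protocol

* **Split.** Stratified 4:1:1 train/validation/test: per stratum of size
  n, floor(4n/6) train, floor(n/6) validation, remainder test — the unique
  simple rounding rule that reproduces all published stratum counts
  (34 → 22/5/7, 24 → 16/4/4, 38 → 25/6/7, 36 → 24/6/6). Strata are class
  labels, optionally crossed with concentration levels.
* **Selection.** Forward sequential selection capped at two features:
  models are fit on training rows and candidates scored by accuracy on the
  pooled training + validation rows; ties break on the lowest canonical
  name; selection stops when no addition strictly improves accuracy. A
  validation-only scoring pool is available behind an argument.
* **Fit.** z-scoring and a logistic model, both computed from training
  rows only. The logistic fit carries a weak L2 penalty (default 1e-3) —
  with one or two features and small cohorts, perfect separation is
  common and the unpenalized MLE diverges. Tests confirm the fit matches
  `glm()` as the penalty vanishes.
* **Decision rule.** The score is the linear decision value; score ≥ 0 is
  classified positive/susceptible — the boundary itself is positive, and
  the logistic link maps it to probability 0.5.
* **Metrics.** Accuracy as the proportion of correct calls over both
  classes, per-class recall, and average precision by step interpolation,
  reported against the random-classifier baseline (the subset's positive
  prevalence: 7/11 ≈ 0.64 and 7/13 ≈ 0.54 for the published test
  partitions).
* **Exposure sweep.** Cross-validated accuracy (default 6 folds, echoing
  the 4:1:1 granularity — the original fold structure is unspecified) as a
  function of drug-exposure duration, with the plateau defined as the
  first duration no later duration beats by more than a tolerance.

Test rows can not leak into development: standardization, selection and
fitting see only train/validation rows, and a test corrupting every test
row verifies the artefacts are bit-identical.

## The synthetic cohort generator

Raw recordings from the original study are not publicly deposited, so the
package ships a seeded generator whose only contract is the statistical
structure the method assumes: two classes distinguishable through
band-limited spectral statistics.

A recording is synthesized in the frequency domain: a hermitian complex
Gaussian spectrum is shaped by the summed PSD of a white floor, a
1/f^alpha component (default alpha = 1, amplitude referenced to 1 Hz, with
a 0.1 Hz floor to keep the DC region finite) and a biquad resonator
magnitude response representing the cantilever resonance. The shaped
spectrum is split at the effect band edges; for positive labels the
in-band part is multiplied by the square root of an exponential onset
profile that relaxes the band power from baseline to `power_ratio` times
baseline with time constant `tau_min` after drug onset. The effect is
therefore *exactly* band-localized, and its time profile has a closed form
the tests integrate as an oracle. A Poisson spike train (half-sine pulses,
exponential amplitudes, random signs) adds intermittent broadband events;
its rate can shift by `spike_rate_ratio` after onset. Synthesis proceeds
in 60 s blocks to bound the FFT working set on hour-scale signals; blocks
are independent exact draws from the target PSD, so only the rare segment
straddling a splice sees any edge effect.

Defaults are desk-scale study conditions, chosen once: 4 kHz sampling
(Nyquist 2 kHz) with the resonance at 1700 Hz mirrors the low-frequency
protocol at 1/15 of the instrument rate — a full-rate 60 kHz × 8 h cohort
(~1.7 G samples per recording) adds nothing to the method's logic; an
18 kHz profile with the resonance at 8500 Hz supports the 7000–8000 Hz
band of the high-frequency protocol. Whether real treated cells raise or
lower band power is not established; `power_ratio` may be set either side
of 1 and the analysis is direction-agnostic.

What the generator does *not* emulate: real attachment-quality drift,
inter-cell heterogeneity within a class, slow non-stationarities of the
medium phase, or any biophysical cell model. Passing end-to-end tests
therefore demonstrate that the pipeline recovers a band-localized effect
of realistic size from realistic noise — not that real cohorts of these
cell lines would classify at the same accuracy.

## End-to-end study conditions and problem sizes

The heavy end-to-end check simulates 20 positive + 20 negative recordings
(30-min medium + 30-min drug at 4 kHz — hour-scale phases shortened
symmetrically, leaving six 5-min windows per phase), drops the in-band
(10–100 Hz) power to 0.25× with a 5-min onset, builds a 297-feature
grammar over four bands, runs the 4:1:1 protocol and requires test
accuracy ≥ 0.9; forward selection's first pick is also checked against the
exhaustive single-feature oracle on a 12-descriptor grammar. The exposure
sweep test uses a lighter cohort (18 recordings at 400 Hz) and asserts a
one-sided property: cross-validated accuracy must not keep improving after
the injected effect's analytic saturation point. With a homogeneous
synthetic cohort, accuracy typically saturates *earlier* than the injected
band-power profile (classes separate as soon as the effect exceeds
estimation noise), so a two-sided match between the accuracy plateau and
the effect's saturation would only hold for a noise level tuned against
the effect size — a calibration this package deliberately avoids.

## Viability module

The resazurin reference assay enters through two pieces: relative
viability, `100 (Abs_exp − Abs_bg) / (Abs_ctrl − Abs_bg)` (control = 100
by construction, values unclipped, invariant to a common absorbance
offset), and a variable-slope four-parameter logistic fit
`v(c) = bottom + (top − bottom) / (1 + (c/IC50)^h)` by nonlinear least
squares. Fitting stays in linear parameter space so zero-concentration
wells enter through the top asymptote without log(0); starting values come
from the data extremes and the half-maximal crossing; bounds are
bottom ≥ −10, top ≤ 150, hill free-sign (whether the original Prism fits
were constrained is unstated; these are declared defaults).
Non-convergence is flagged on the result, not thrown. The reference IC50
values for the ovarian pair (0.602 µM sensitive, 6.189 µM resistant) are
context for choosing nanomotion drug concentrations; the underlying
plate-reader points are not machine-readable, so recovery is demonstrated
on simulated curves instead (noiseless round-trip within 1%, bias under 5%
across 200 noisy replicate simulations).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  sampling_rate = 500, blank_min = 0, medium_min = 10, drug_min = 10,
  resonance = list(freq_hz = 180, q_factor = 15, amplitude = 0.4),
  effect = list(band_lo_hz = 10, band_hi_hz = 50, power_ratio = 0.3,
                tau_min = 2),
  spikes = list(rate_hz = 0))
cs <- cohort_spectrograms(10, 10, cfg, seed = 7, window_min = 2,
                          welch = welch_params(overlap_frac = 0))
g <- feature_grammar(bands = list(c(0, 10), c(10, 50), c(50, 100)),
                     intervals = list(c(0, 10), c(10, 20)),
                     kinds = c("band_power", "spikiness"),
                     combinators = c("value", "ratio"))
fm <- build_feature_matrix(cs$spectrograms, g, labels = cs$labels)
split <- stratified_split(cs$labels, seed = 1)
sel <- forward_select(fm, split)
model <- fit_classifier(fm, split, sel$selected)
evaluate_classifier(model, fm, split, "test")
```

## Known limitations

* The "modification" of Welch's method beyond quantiles-in-place-of-mean
  is undocumented in the source protocol; segment length, taper and
  overlap here are declared defaults, not reconstructions.
* Quantiles over overlapping (correlated) segments carry a documented
  variance bias; no decorrelation step is invented.
* The published real-data accuracies (100%/90.9% colon; 84.6% ovarian
  test with 100% resistant recall; the 84% plateau at 4 h 15 min) concern
  undeposited recordings and are documentation context only — nothing in
  this package claims to reproduce them.
* File I/O covers the package's own IEEE-float WAV dialect (32- and
  64-bit) with a JSON sidecar; no vendor instrument formats are parsed.
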