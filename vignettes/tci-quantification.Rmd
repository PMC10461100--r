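---
title: "Quantifying transcuticular calcium imaging screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcuticular calcium imaging screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcikit)
```

## The measurement problem

Deorphanizing an insect odorant receptor (OR) means finding the odorants
that activate it. A widely used platform expresses the candidate OR in
Drosophila "empty neurons" — olfactory sensory neurons whose own receptor
has been removed — and reads the neurons' responses out either by
single-sensillum electrophysiology (SSR) or, as here, by imaging a
genetically encoded calcium indicator (GCaMP6) through the intact antennal
cuticle: transcuticular calcium imaging (TCI). One recording is a short
fluorescence movie of the antenna; a region of interest (ROI) drawn around
the antenna is averaged per frame into a single fluorescence trace.

The canonical protocol, fixed throughout this package as defaults and
fully configurable, is **100 frames at 5 Hz** (20 s) with a **1 s odor
stimulus at frames 16–20**, i.e. 3 s into the recording. All user-facing
frame indices are 1-based with inclusive windows, so "frames 17–31" is 15
frames.

## From raw trace to response amplitude

Three steps turn a raw trace $F(t)$ into a scalar response:

1. **Relative change.** $\Delta F/F_0 = (F - F_0)/F_0$, with $F_0$ the
   mean over the five frames immediately preceding stimulus onset (frames
   11–15). By construction the uncorrected trace has exactly zero mean
   over its baseline window — a property the unit tests assert as an
   algebraic identity. A non-positive $F_0$ signals a dead or empty ROI
   and is an error, not a silent NaN.
2. **Photobleaching correction.** Continuous 488 nm excitation bleaches
   GCaMP over the 20 s recording, superimposing a slow decay on every
   trace. A *blank* recording — same acquisition, no stimulus — measures
   that decay alone; its $\Delta F/F_0$ curve is subtracted frame by frame
   from every stimulated curve. When a fly has several blanks their curves
   are averaged; a global average across flies is available as a fallback
   (`blank_scope = "global"`) for recordings without their own blank.
3. **Windowed amplitude.** Calcium signals are slow, so the response
   amplitude is the mean $\Delta F/F_0$ over the 15 frames (3 s) following
   stimulus start — frames 17–31 — reported in percent.

`build_response_matrix()` composes the three steps over a list of
recordings into a flies × stimuli amplitude table. Solvent controls are
deliberately retained as columns: they are the negative controls against
which odorant responses are judged, not a quantity to subtract.

### Why subtraction happens in ΔF/F₀ space

Both the stimulated curve and the blank are normalized to their own
baselines before subtraction. Under a multiplicative bleach model (see the
simulator below) this makes blank subtraction a close approximation rather
than an exact inverse — the residual is the bleach attenuation accumulated
between the baseline window and the response window, about 4 % of the
amplitude at a 30 s bleach time constant. The test suite quantifies this
residual (the corrected amplitude must land within 0.5 percentage points
of the kernel prediction at zero noise) instead of pretending the
correction is exact.

## Tuning breadth: lifetime sparseness

A receptor's response spectrum over a panel of $n$ stimuli is summarized
by lifetime sparseness

$$S = \frac{1}{1 - 1/n}\left(1 -
  \frac{\left(\sum_i r_i/n\right)^2}{\sum_i r_i^2/n}\right),$$

which is 1 when exactly one stimulus elicits a response and 0 when all
respond equally. The formula is undefined for negative $r_i$, so negative
amplitudes (measurement noise around zero for non-ligands) are clamped to
0 before evaluation — only for sparseness, never for correlation analyses.
Solvent controls are excluded from the panel by default. $S$ is invariant
under positive rescaling of the profile, so it can be compared across
modalities with different units (% ΔF/F₀ vs spikes/s).

## When does the calcium signal reflect the spike tuning?

With an external per-stimulus reference profile (typically SSR spike-rate
amplitudes for the same receptor), `framewise_crosscorrelation()` computes
at **every frame** the squared Pearson correlation across stimuli between
the calcium values at that frame and the reference amplitudes. This is a
per-frame correlation of tuning profiles, not a signal-processing lag
correlation: the question it answers is *at which point in time the slow
calcium signal best reproduces the fast electrophysiological tuning*.
Frames with zero variance across stimuli (before stimulus onset in clean
data) have no defined correlation and are reported as `NA`; among defined
values, ties at the maximum resolve to the earliest frame. Calcium
profiles are across-fly means; stimulus matching against the reference is
by exact label with an optional alias table, and unmatched stimuli are
dropped with a warning.

## Dose–response: EC₅₀ and Hill slope

Each fly's amplitudes across a dose ladder are first normalized — highest
response (over all doses, not necessarily the top dose) to 100 %, solvent
response to 0 % — and then fit with the variable-slope logistic

$$R(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
  {1 + (EC_{50}/d)^h},$$

optimized over $\log_{10} EC_{50}$ by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`). The solvent point never enters the fit (log of
zero dose is undefined); it acts only through normalization. With
normalized input the asymptotes are fixed at 0/100 by default. Numerical
choices: the EC₅₀ start is where the curve crosses midway between its
extremes (linear interpolation on log dose), with a small grid of
fallback starts and best-deviance selection; bounds are EC₅₀ within
[min dose/100, max dose × 100] and $h \in [0.05, 20]$; an EC₅₀ outside
[min dose/10, max dose × 10] is flagged extrapolated. Flat series (zero
dynamic range) and non-responding flies (maximum not above solvent) are
errors and exclusions respectively, not silent fits.

Fitting is per fly, then summarized as mean ± SEM across flies — the form
in which EC₅₀ sensitivity is conventionally reported; `fit_hill_pooled()`
offers the one-curve-per-panel alternative, which is more stable when
individual flies contribute few informative doses. `compare_curves()`
reports descriptive differences between modalities (Δ mean log₁₀EC₅₀,
Δ mean Hill slope, per-dose means ± SEM); hypothesis testing is out of
scope here.

## Recording longevity

Imaging through the cuticle is non-invasive, so one fly can be stimulated
every 2 min for hours. `stimulations_to_half_max()` counts how many
stimulations stay at or above 50 % of the series maximum before the first
one that drops below it, with right-censoring when the series never
drops. The count is exact on clean series (a geometric decay
$10 \cdot 0.9^{j-1}$ gives exactly 7, matching direct enumeration) but is
deliberately conservative on noisy ones: a single noise dip ends the
count, so on realistic series it reads below the crossing point of the
*expected* decay. That is a property of the first-drop rule itself, worth
knowing when comparing against counts read off averaged curves.

## The synthetic-recording generator

No raw recordings ship with the package, so every pipeline stage is
exercised against `tci_scenario()` simulations with the statistical
structure the analysis assumes:

$$F(t) = B\,e^{-t/\tau_{bleach}}\,(1 + a\,k(t)) + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \sigma^2)$$

* **Bleach is multiplicative** (it attenuates baseline and signal alike,
  as photodestruction of fluorophores does), which is exactly what makes
  ΔF/F₀-space blank subtraction approximate and the correction worth
  testing quantitatively.
* **The transient kernel** $k(t)$ is a boxcar over the stimulus window
  convolved with $(1 - e^{-t/\tau_{rise}})e^{-t/\tau_{decay}}$, normalized
  to unit peak; it is exactly zero at and before onset. Presets "GCaMP6s"
  (rise 0.4 s, decay 2.5 s) and "GCaMP6m" (rise 0.2 s, decay 1.2 s) encode
  only the ordering *6s slower than 6m*; they are order-of-magnitude
  placeholders, not measured constants, and tests never treat them as
  ground truth beyond being the generator's own parameters.
* **Latent tuning** $a_s$ (peak ΔF/F fraction per odorant; default a
  graded 14-odorant spectrum with a 0.10 best ligand, giving window
  amplitudes of a few percent) is shared with a simulated SSR channel
  through `reference = ssr_gain · a_s + noise`, so calcium–SSR
  cross-correlation has a known ground truth.
* **Dose scenarios** draw the activation from a Hill curve
  (default EC₅₀ = 1 µg, h = 2) over the standard 7-dose ladder
  100 pg–100 µg on filter paper.
* **Variability** has three scales chosen to mirror the experiment:
  additive sensor noise per frame (σ = 10 camera units on a baseline of
  1000, i.e. 1 %); an across-recording multiplicative response gain with
  CV 10 % (biological variability between flies — also the noise model of
  the dose-recovery experiments, where it is the sole noise source so that
  amplitude noise is exactly CV 10 %); and a much smaller within-fly
  trial-to-trial gain (CV 3 %) for repeated stimulations of the same
  neurons, used by the adaptation series. Shot noise and movement
  artifacts are not modeled.
* **Adaptation** across repeats follows
  $a_j = a_1\,(f + (1-f)e^{-(j-1)/\kappa})$ with defaults $f = 0.2$,
  $\kappa = 128$, placing the expected half-max crossing near
  stimulation 126 at the 2-min inter-trial interval.
* **Determinism**: every simulate function draws from a private RNG
  stream derived from the scenario seed (per-recording sub-seeds), so a
  scenario reproduces bit-identically and never perturbs the caller's
  RNG state.

What passing tests on these simulations shows — and what it does not: the
pipeline recovers known amplitudes, tuning, EC₅₀/h and correlation
structure from data that *obey the generative model*. Real recordings add
movement, focus drift, heterogeneous bleaching and non-Gaussian noise that
the generator deliberately omits; the tests validate the quantification
arithmetic, not robustness to those artifacts.

## Problem sizes and test design

The test suite checks exact identities where they exist (baseline zero
mean, self-subtraction, sparseness endpoints, the geometric longevity
count) and otherwise compares against independent oracles: brute-force
masked means and Pearson correlations computed from raw sums, an
FFT-based convolution for the kernel, and closed-form generative
predictions at zero noise. Stochastic properties use fixed seeds and
pre-stated tolerances: amplitude unbiasedness over 200 simulated flies,
dose-parameter recovery over 50 replicate 11-fly panels (median
log₁₀EC₅₀ within ±0.15, median Hill slope within ±25 %), and the
pre-stimulus vs post-onset correlation ordering over 10 seeds. These sizes
keep the full suite under a minute while leaving the Monte Carlo margins
comfortably wide.

## File formats

Stacks are multi-frame grayscale TIFFs with a JSON sidecar for the frame
rate (acquisition metadata is never inferred from TIFF tags); integer
count data round-trips losslessly at 16 bit, other data at 32 bit with a
stored scale. ROIs are label images or polygon JSON; the pixel mask is
canonical. Traces travel as long-format CSV (`recording_id, frame, F`)
plus a per-recording metadata CSV; reading validates frame contiguity and
duplicates, naming the offending recording and frame. The pipeline writes
wide + long response-matrix CSVs, a tuning JSON, dose-fit CSVs, a
longevity CSV and a text summary, all stamped with a config hash and the
package version.

## Known limitations

* Blank subtraction corrects the average bleach trajectory; it cannot
  correct fly-specific deviations when a global blank is used.
* The per-fly Hill slope is weakly identified on 7-dose ladders with only
  2–3 points on the transition; prefer `fit_hill_pooled()` or report the
  across-fly mean with its SEM rather than individual slopes.
* The first-drop longevity rule is noise-conservative (see above).
* No motion correction, ROI segmentation, spike inference, or inferential
  statistics — these are upstream or downstream of this package's scope.
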