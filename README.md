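# tcikit

Quantification pipeline for **transcuticular calcium imaging (TCI)**
screens of insect odorant receptors. TCI images GCaMP fluorescence of
olfactory sensory neurons through the intact antennal cuticle of
Drosophila "empty neuron" flies expressing a heterologous receptor; it
trades the single-spike resolution of single-sensillum recordings (SSR)
for a non-invasive preparation that survives hours of repeated
stimulation and parallel imaging of several flies. This package turns the
raw recordings of such a screen into receptor characterizations, and
ships a generative simulator so the whole pipeline is testable without
any recordings.

## What it computes

Given per-ROI fluorescence traces (or TIFF stacks plus ROI masks) with
stimulus metadata, under the canonical protocol of 100 frames at 5 Hz
with a 1 s stimulus at frames 16–20:

* **ΔF/F₀ traces** — (F − F₀)/F₀ with F₀ the mean over the 5 pre-stimulus
  frames (11–15), bleach-corrected by subtracting the ΔF/F₀ decay curve of
  a no-stimulus blank recording.
* **Response amplitudes** — mean ΔF/F₀ (in %) over the 15 frames (3 s)
  after stimulus start (frames 17–31), assembled into a flies × stimuli
  response matrix with solvent controls retained as negative controls.
* **Tuning** — lifetime sparseness
  S = (1 − (Σrᵢ/n)²/(Σrᵢ²/n)) / (1 − 1/n) ∈ [0, 1] (1 = responds to a
  single stimulus; negatives clamped to 0), and a frame-resolved squared
  Pearson correlation between the calcium tuning profile and an external
  SSR reference profile, answering *when* the calcium signal best
  reproduces the spike tuning.
* **Dose–response** — per-fly normalization (max → 100 %, solvent → 0 %)
  and a variable-slope logistic fit
  R(d) = bottom + (top − bottom)/(1 + (EC₅₀/d)ʰ) over log₁₀ dose,
  summarized as EC₅₀ and Hill slope mean ± SEM across flies.
* **Longevity** — the number of repeated stimulations (2 min apart)
  sustained at ≥ 50 % of the maximum response, with censoring.

## Worked example

A simulated 16-fly screen of a generalist-type receptor against a
14-odorant panel, with its paired simulated SSR reference:

```r
library(tcikit)

sc    <- tci_scenario(seed = 11)              # canonical protocol defaults
report <- run_pipeline(run_config(
  scenario  = sc, n_flies = 16,
  dose      = list(doses = 10^seq(-4, 2)),    # 100 pg .. 100 ug
  longevity = list(n_stims = 180)))
print(report)
```

```
16 flies x 15 stimuli; response window frames 17-31

Mean response amplitudes (% dF/F0, mean +/- SEM across flies):
  solvent                  0.02 +/- 0.21  [solvent]
  odorant_01               6.39 +/- 0.22
  odorant_02               5.43 +/- 0.26
  odorant_03               4.06 +/- 0.20
  ...
  odorant_14               0.09 +/- 0.18

Lifetime sparseness S = 0.523 (n = 14 odorants)
Peak calcium-reference correlation r2 = 0.973 at frame 20 (14 stimuli)
Dose-response (n = 16 flies): EC50 = 0.992 +/- 0.098 ug, Hill slope = 4.84 +/- 1.2
Longevity: 45 stimulations to half-max (of 180 applied)
```

Reading the numbers: the best ligand produces a ~6.4 % ΔF/F₀ response
against a solvent control at zero; the graded spectrum yields an
intermediate sparseness (S ≈ 0.5, broad tuning); the calcium tuning
correlates with the simulated SSR reference at r² ≈ 0.97, peaking shortly
after odor onset; the fitted EC₅₀ recovers the generative 1 µg (the
per-fly Hill slope is weakly identified on a 7-dose ladder — see the
vignette); and the first noise dip below half-max ends the longevity
count at stimulation 45, well before the expected-decay crossing near
126 — the first-drop rule is conservative on noisy series.

The vignette (`vignettes/tci-quantification.Rmd`) documents the model,
the parameter choices and the simulator's scope in detail. A thin CLI
wrapper lives in `inst/scripts/tci.R`
(`Rscript tci.R run --scenario scenario.json --out dir/`).

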