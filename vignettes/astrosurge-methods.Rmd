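---
title: "Methods: subcellular astrocyte calcium analysis and the spatial threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subcellular astrocyte calcium analysis and the spatial threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrosurge)
```

## The scientific problem

Cortical astrocytes respond to sensory input with intracellular calcium
signals that are organised at several spatial scales: small subcellular
*domains* within the branched *arborization* respond first, and only when
enough of them are active does the *soma* respond, after which a whole-cell
*calcium surge* propagates back out through the arborization. `astrosurge`
implements the complete analysis workflow for two-photon recordings of this
process — structural segmentation, ΔF/F₀ event detection, estimation of the
*spatial threshold* (the fraction of active domains required for somatic
activation) by a Heaviside step fit, and the spatiotemporal characterisation
of the surge — together with a synthetic-data generator that provides ground
truth for every stage.

The in vivo recordings such an analysis was designed for are not
redistributable at package scale, so every empirical claim made by this
package is a *parameter-recovery* claim on synthetic data: the generator
plants a known threshold, known kinetics and known propagation structure, and
the test suite and `scripts/acceptance.R` verify that the analysis recovers
them.

## Segmentation model

Each astrocyte territory (a manually or externally outlined mask) is
converted to polar coordinates around a user-supplied soma seed
(`polar_transform()`): `r = sqrt((x − x_s)² + (y − y_s)²)`,
`θ = atan2(y − y_s, x − x_s)`. The radial fluorescence profile
(`ring_profile()`) averages the structural channel over concentric rings of
width one pixel (width exposed as a parameter; one pixel is the finest
profile the data support). Scanning outward, the **soma radius** is the inner
radius of the first ring whose mean falls below 50% of the centre ring's
fluorescence (`find_soma()`); profiles that never cross half-max mark the
cell as failed rather than guessing. The **arborization** is every non-soma
pixel at least 0.25 ring-standard-deviations above its ring median
(`find_arborization()`) — the SR101-positive criterion. On a symmetric
intensity distribution this retains roughly the brighter half of each ring,
which is the intended behaviour on real images, where bright processes stand
out of a dim background; on the synthetic images it subsamples the
arborization, and the measurement consequences are discussed below. The ring
SD is the sample SD of the pixel values in the ring. **Domains** are the
cells of a square grid of side `floor(4.3 µm / pixel size)` pixels anchored
at the top-left of the territory bounding box, clipped to arborization
pixels; clipped domains keeping fewer than 4 pixels are discarded because a
trace averaged over fewer pixels is dominated by single-pixel noise.

## Signal model

Traces are per-frame ROI means normalised as `(F − F₀)/F₀` with `F₀` the
mean over the 10 s preceding stimulation (`extract_trace()`); the
normalisation makes every downstream quantity invariant to detector gain. An
**event** starts at the first of at least 2 consecutive frames exceeding the
baseline mean by 3 baseline SDs within the response window and ends when the
trace falls back below that level (`detect_events()`). The amplitude rule is
the field's standard 3·SD criterion; the 2-frame persistence requirement is
this package's choice to suppress single-frame noise spikes at 0.2–0.5 s
sampling. Onsets are the first supra-threshold frame, not back-extrapolated.
Kinetics (10–90% rise, 90–10% decay, latency) interpolate linearly between
frames; a decay that never returns to 10% is censored, not extrapolated.
"Basal" activity is the same detector run on a pre-stimulus window of equal
length. The 3·SD rule is applied to ΔF/F₀; under the normalisation above
this is equivalent up to scale to applying it to raw fluorescence.

The detector's false-positive rate on pure noise is not the naive Gaussian
tail: the threshold is estimated from only 20 baseline frames, so
`fp_rate_analytic()` integrates the exceedance probability over the sampling
distribution of the baseline mean and SD (normal × chi) before applying the
2-consecutive-frame run correction. Monte-Carlo simulation in the test suite
agrees with this rate (~0.7% per 60 s trace).

## The spatial threshold

Each astrocyte contributes a point `(a, S)`: `S ∈ {0, 1}` is whether its
soma responded and `a` is its fraction of active domains — the fraction
active *before soma onset* for soma-active cells, and the whole-window
fraction otherwise (using the whole window for `S = 1` cells would let the
post-soma surge inflate `a` for exactly those cells). `fit_heaviside()`
minimises `Σᵢ (Sᵢ − H(aᵢ, a_T))²` over a candidate grid consisting of the
midpoints between consecutive sorted unique `a` values plus 0 and 1 — an
exhaustive grid up to fit equivalence. Ties go to the smallest candidate (a
conservative threshold). For binary `S` and `H` squared and absolute error
coincide. `R²` is `1 − SSE/SST` on the 0/1 labels. The implementation uses
cumulative class counts (O(n log n)); the test suite checks it against an
exhaustive brute-force scan on 1,000 random instances.

**Confidence intervals** use a case-resampling bootstrap with one
modification: the threshold is a boundary-type statistic, and on
well-separated data plain resampling can never place probability mass inside
the gap containing the estimate, which makes the percentile interval
anti-conservatively narrow (we measured ~76% coverage at nominal 95%). The
resampled fractions are therefore jittered with a Gaussian kernel whose SD is
twice the mean spacing of the observed fractions — a smoothed bootstrap,
with the bandwidth calibrated once on synthetic separated-step data to
restore near-nominal coverage (98–100% in 50-experiment calibration runs).
`smooth = FALSE` gives the plain interval. Replicates whose resample
contains only one soma class are dropped and counted; more than 20% of them
flags the interval unreliable. A per-stimulus-condition consolidation
(threshold per condition, spread across conditions) is available through the
population report.

The sigmoid fit of soma amplitude versus `a` (`fit_sigmoid()`, a
4-parameter logistic by Levenberg–Marquardt with a small grid of starting
values) is a cross-check: on step-like data its inflection agrees with the
Heaviside threshold.

## Spatiotemporal structure of the surge

Domain events are partitioned into `pre_soma` / `post_soma` by comparison
with the soma onset, or `no_soma` when the soma stayed silent
(`classify_phases()`); the partition is exhaustive and exclusive. Pairwise
clustering statistics (mean centroid distance, mean inter-onset interval)
are computed per astrocyte and phase over all unordered pairs
(`surge_metrics()`), with distances between domain *centroids* — domains are
≤ 4.3 µm squares, so the centroid approximation errs by at most half a
diagonal. Analyses of surge structure restrict soma-active cells to *early
responders* (soma onset before the population median), so that late,
possibly neighbour-driven activations do not blur the propagation pattern.

Propagation direction is measured by regressing onset (relative to soma
onset) on radial distance from the soma centre
(`onset_radius_regression()`): a negative pre-soma slope is the centripetal
pattern (distal domains respond sooner), a positive post-soma slope the
centrifugal surge. The default mode bins radii (5 µm) and regresses bin
means, mirroring population-level analyses; raw-point regression is
available. Slopes are reported in s/µm.

The **soma-driver model** (`glm_soma_drivers()`) is a binomial-logit GLM of
`S` on three z-scored per-cell descriptors: percent area, mean pairwise
distance, mean pairwise time. A logit link is the natural choice for the
binary outcome; predictors are z-scored so the coefficient magnitudes are
comparable. The predictors are computed from the activity *leading up to*
the soma decision (pre-soma events for soma-active cells): including
post-soma events would leak the outcome into the predictors, since surge
recruitment exists only in soma-active cells. Per-predictor significance
uses likelihood-ratio tests, which remain informative near separation where
Wald statistics collapse. Because a thresholded soma is close to separable
from the percent area, the default fit adds two weighted pseudo-observations
at the predictor centre — a weakly-informative prior that bounds the
likelihood; in simulation this restored the nominal type-I rate of the
nuisance-predictor tests (a pure-noise predictor was flagged ~10% of the
time without it, ~0–5% with it) while leaving the area effect intact.
Complete separation of the unregularized fit is still detected and reported;
`regularize = FALSE` gives the plain ML fit.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are the conditions
everything in this package is validated under, and they are not revisited
per experiment:

* **Acquisition**: 1.43 µm pixels (a 366 µm field at 256 px), 0.5 s frames,
  60 s movies, stimulation from 10 s to 30 s, 10 s baseline.
* **Geometry**: territory radius 25 µm (a ~50 µm territory), soma plateau
  radius 5 µm, 4.3 µm domain grid.
* **Threshold rule**: ground-truth spatial threshold `theta_true = 0.226`;
  the soma activates iff the realized fraction of domains active before the
  soma decision is ≥ `theta_true`. Per-astrocyte stimulus levels are drawn
  uniformly from [0.05, 0.6] and map to per-domain activation probabilities
  through a monotone `p_domain` (identity by default), so realized fractions
  densely span both sides of the threshold.
* **Timing**: pre-soma domain onsets follow
  `stim + 11.1 s − 0.1 s/µm · (r − r̄) + N(0, 0.5 s)` (centripetal: distal
  earlier), the soma follows the mean domain latency by 2.1 s, and
  domains recruited by the surge (probability 0.28 per remaining domain)
  activate at `soma onset + r / 5 µm s⁻¹` (centrifugal). Pre-soma onsets are
  clamped to lead the soma by at least two frames, so that the slightly
  larger detection delay of small-ROI traces cannot flip the measured event
  order.
* **Events**: piecewise-linear (triangular) waveforms with 10–90% rise
  5.7 s and 90–10% decay 4.8 s for domains/arborization, 3.5 s and 4.3 s for
  somas, amplitude 2.0 ΔF/F₀ (typical of strong sensory-evoked GCaMP6f
  responses). A triangular ramp maps the configured 10–90/90–10 times onto
  segment durations exactly (`T = t_kin / 0.8`); a difference of two
  exponentials was rejected because that family cannot realise a rise time
  longer than the decay time, which the arborization kinetics require.
* **Structural channel**: per astrocyte a radial profile — plateau 1.0 to
  the soma radius, steep linear fall to 0.15 over 1.5 µm, shallow decay to
  0.10 at the territory edge — plus Gaussian noise (SD 0.1, i.e. SNR 10,
  appropriate for a time-averaged structural stack). The half-max radius is
  closed-form (`analytic_half_max_um()`), and the steep fall spans the whole
  plausible range of the noisy half-max reference, so the estimated soma
  radius stays within one ring of the analytic value. The functional soma
  compartment is the structurally defined soma (everything inside the
  half-max radius), and domains begin beyond a 1.5 µm clearance band so that
  a soma mask recovered with ±1 ring of discretization error never overlaps
  responding domains.
* **Functional channel**: `baseline_f · (1 + ΔF/F) + noise`, i.i.d. Gaussian
  per pixel and frame (SD 0.1 ΔF/F units); no photobleaching or motion — the
  analysis assumes registered, baseline-stable movies.
* **KO mode** emulates IP₃R2-knockout astrocytes: per-domain activation
  probability capped at 0.145, realized per-cell fractions hard-capped below
  `theta_true − 0.05`, somas never activate. The 0.05 margin encodes that
  knockout cells sit well below threshold, and keeps measured fractions
  (which include a ~1% per-domain false-positive rate) below the threshold
  too; the mean active fraction stays at the ~14.5% calibration level.
* **Determinism**: all draws derive from `seed` (structure, movie noise and
  events use separate derived streams, so wild-type and KO runs of one seed
  share an identical structural channel).

`simulate_ground_truth()` is table-level and cheap (no pixels), which is
what the large parameter-recovery experiments use; `simulate_population()`
renders the images. `observe_responses()` adds a detection-noise observation
model (per-domain miss/false-positive rates) without rendering, used where
an experiment needs measured-like data at scale — notably the soma-driver
recovery experiment, where noiseless ground truth would be perfectly
separated by construction (soma state is a deterministic function of the
true fraction) and a logistic model would be degenerate.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
radial structural profiles, threshold-gated somatic activation, pre/post
partition, centripetal/centrifugal onset gradients, realistic kinetics and
detector-relevant noise. It does not emulate photorealistic microscopy,
motion, bleaching, sponge-like fine morphology, overlapping territories, 3D
volumes, or neuronal signals. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated under the stated model — not that
the model captures every property of in vivo data.

One measurement property deserves emphasis. The SR101-positive rule keeps
roughly 45% of arborization pixels on the synthetic images, so a measured
cell's active fraction is computed from about half of its true domain grid.
This subsampling adds ~0.04–0.05 SD of noise to each cell's `a` — exactly as
it does in real recordings, where domains are likewise defined only on
SR101-positive pixels. Because the soma decision is driven by the *true*
fraction, the measured classes overlap, and the argmin of the step-fit error
settles at the crossing point of the two class densities, which sits
slightly *below* the true threshold under the conservative smallest-candidate
tie rule. In image-based end-to-end runs at 240–480 cells the recovered
threshold is accordingly biased by about −0.01 with a spread of ±0.02
(total error within ±0.05); table-level recovery without measurement
subsampling is unbiased and within ±0.02 at the 995-cell cohort size. The
end-to-end pipeline test asserts the ±0.05 envelope and the test suite
asserts the ±0.02 recovery on ground-truth responses; both figures are
reproduced by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Candidate grid midpoints make the step fit exhaustive; ties take the
  smallest candidate.
* Kinetics interpolate linearly; events are censored rather than
  extrapolated when a limb is incomplete.
* Cells with no half-max crossing, an empty arborization, non-positive F₀,
  or fewer than 10 domains are excluded with a logged reason, never guessed.
* Degenerate threshold inputs (one soma class) return an explicit failure;
  bootstrap replicates that degenerate are dropped and counted.
* TIFF storage is [0,1]-normalised by an affine map recorded in a YAML
  sidecar; ΔF/F₀ is invariant to it.
* All randomness is seeded; identical config + seed reproduce bit-identical
  outputs, and the pipeline manifest records an MD5 hash of every artifact.

## Problem sizes used by the validation suite

The test suite and acceptance script run, on one CPU in a few minutes:
1,000-instance oracle equivalence for the step fit; 60 cohorts of 995 cells
for threshold recovery at `theta_true` ∈ {0.10, 0.226, 0.40}; 50
bootstrap-coverage experiments at 995 cells; 100 rendered single-astrocyte
segmentations; 1,000 pure-noise detector traces plus injected-event and
noiseless-kinetics checks; 40-seed propagation-sign recovery; an image-based
30-cell knockout pipeline; and 20-seed soma-driver recovery at 200 cells.

## Known limitations

* The pipeline analyses single 2D fields; 3D volumes, motion correction and
  bleach correction are out of scope.
* Territory outlining is an input (labeled mask), not computed.
* The smoothed-bootstrap bandwidth is calibrated for threshold-like
  separated data; for heavily overlapping data the plain bootstrap is
  already well-behaved and `smooth = FALSE` may be preferred.
* The GLM reports a logit-link model; the identity-link alternative of a
  "general linear model" on a binary outcome is not provided.
* Slow-inward-current (patch-clamp) analyses are out of scope; the
  threshold fit can of course be applied to externally supplied
  `(a, S)` tables from such experiments via `fit_heaviside()`.
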