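# astrosurge

Subcellular analysis of astrocyte calcium imaging: soma/arborization/domain
segmentation, ΔF/F₀ event detection, estimation of the **spatial threshold**
for somatic activation, and characterisation of the **calcium surge** that
follows it.

## The problem and who this is for

Two-photon recordings of cortical astrocytes (GCaMP functional channel,
SR101-like structural channel) show calcium activity organised in small
subcellular *domains* within the astrocyte's arborization. Somatic
activation is not graded: the soma responds when the fraction of active
domains crosses a threshold, and somatic activation is followed by a
whole-cell *calcium surge* that recruits further domains centrifugally. This
package is for imaging labs and analysts who need a reproducible, scriptable
pipeline for this style of analysis — from raw TIFFs plus territory
outlines to per-cell response tables, threshold estimates with confidence
intervals, and propagation statistics — together with a synthetic-data
generator that makes every stage testable against known ground truth.

## The model at the core

Each astrocyte `i` contributes a binary soma response `S_i` and a fraction
of active domains `a_i` (measured before soma onset for responding cells).
The spatial threshold `a_T` is estimated by fitting a Heaviside step

```
H(a) = 0 if a < a_T,  1 if a ≥ a_T        (error = Σ_i (S_i − H(a_i))²)
```

over an exhaustive candidate grid, with a smoothed case-resampling bootstrap
for the 95% CI and a 4-parameter logistic fit of soma amplitude vs `a` as a
cross-check. Upstream, the structural channel is segmented by radial
profiling (soma = first ring below 50% of centre fluorescence; arborization
= pixels ≥ ring median + 0.25 SD; domains = 4.3 µm grid cells clipped to
arborization pixels), and events are detected at baseline mean + 3 SD
sustained for 2 frames. Downstream, domain onsets are split into
pre-/post-soma phases, pairwise distance/time clustering is computed per
phase, onset-vs-radius regressions measure the centripetal (pre-soma,
negative slope) and centrifugal (post-soma, positive slope) propagation, and
a logistic model identifies which per-cell descriptor drives somatic
activation.

## Worked example

```r
library(astrosurge)

# a synthetic field with a known spatial threshold of 0.226
cfg <- sim_config(n_astrocytes = 25, seed = 42)
pop <- simulate_population(cfg)
res <- run_pipeline(pop, "out", seed = 1)

print(fit_heaviside(res$responses))
```

```
<threshold_fit> a_T = 0.2071 (20.7%), R^2 = 0.675, n = 25
```

The planted threshold is 22.6% of active domains; with a single 25-cell
field the step fit lands at 20.7%, within the measurement spread that the
methods vignette quantifies (pooling a few fields, or fitting the
ground-truth response table, tightens it to within ±2 points). The surge
statistics from the same run:

```r
res$surge$regression_pre$slope    # -0.0689  s/um  (centripetal: distal first)
res$surge$regression_post$slope   # +0.2481  s/um  (centrifugal, ~1/speed)
```

The pre-soma slope is negative — distal domains respond before proximal
ones — and the post-soma slope approximates the inverse of the configured
outward surge speed (5 µm/s).

`out/` contains the domain catalog, event table,
per-cell responses, threshold JSON, surge metrics, figures and a manifest
with an MD5 hash of every artifact; rerunning with the same seed reproduces
the tables bit for bit.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/astrosurge", package="astrosurge"))')" \
    simulate --out pop --seed 7 --n 25
# then: ... run-all --in pop --out results --seed 1
```

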