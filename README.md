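# vesiquant

Quantitative analysis of vesicle exocytosis in live-cell fluorescence
imaging of neurons.

Sensory neurons signal through two vesicle types: small synaptic vesicles
(SVs) that drive fast synaptic transmission, and large dense-core vesicles
(LDCVs) that release neuropeptides from the soma under strong stimulation.
Measuring either process from microscopy data requires a chain of
quantitative steps — punctum detection, trace extraction, event
classification, normalization — that are usually performed by hand in
ImageJ and are hard to reproduce. `vesiquant` packages those analyses as
tested, scriptable R functions, and pairs every stage with a synthetic-scene
generator that records complete ground truth, so the whole pipeline is
validated against known answers rather than by eye.

## What it computes

* **LDCV exocytosis (TIRF):** detects immobile fluorescent puncta at the
  cell footprint, classifies fusion events from their intensity traces —
  *full fusion* (trace falls from ≥50% to ≤10% of its running median within
  200 ms without recovery) versus *kiss-and-run* (≥1.5× transient rise for
  ≤0.5 s with a ≥1.3× spot-width increase, the released cargo cloud, then
  loss) — and reports cumulative exocytosis normalized to the cohort mean
  footprint area, vesicle densities, release probability
  (events / docked vesicles), and responder fractions.
* **Synaptic transmission (SypHy):** identifies synapses as immobile puncta
  with a sharp NH₄Cl plateau, normalizes each trace to its own total-pool
  plateau (making results independent of reporter expression), detects the
  response time as the first sustained crossing of baseline mean + 2 SD, and
  classifies synapses as pre-stimulus / synchronized (within 1 s of onset) /
  delayed / nonresponsive.
* **Vesicle morphometry (STED):** fits the correlated elliptical Gaussian

  f(x,y) = A·exp[ −1/(2(1−cor²)) ( ((x−x₀)/x_width)² + ((y−y₀)/y_width)²
  − 2·cor·(x−x₀)(y−y₀)/(x_width·y_width) ) ] + offset

  to vesicle patches by bounded least squares and converts widths to
  nanometer sizes (FWHM = 2 · width · pixel size).
* **Colocalization and mapping:** Manders coefficients M₁, M₂ restricted to
  neurite ROIs, synaptic-punctum selection by a dual-channel ≥1,000 AU
  excess over the local neurite, 3-px-wide line profiles aligned on a
  reference channel before averaging, synaptic enrichment folds, synapse
  densities and distances to the nearest soma membrane.
* **Ratiometric calcium (Fura-2):** 350/380 ratio images with validity
  masking and conversion [Ca²⁺] = K_d·β·(R − R_min)/(R_max − R) under an
  in-situ calibration (defaults R_max 3.73, R_min 0.64, K_d 350 nM,
  β 6.73); saturated ratios are masked, not capped.

## Worked example

Simulate a TIRF movie with three scheduled fusion events, analyze it, and
compare with the generator's truth:

```r
library(vesiquant)

cfg <- simulation_config(
  noise_sd = 100, background = 500, seed = 42,
  event_schedule = data.frame(spot = 1:3, time_s = c(2, 4, 6),
                              class = c("full_fusion", "kiss_and_run",
                                        "full_fusion")))
sim <- simulate_ldcv_movie(cfg)

movie <- subtract_background(sim$movie)
footprint <- roi_polygon(rbind(c(-0.5, -0.5), c(-0.5, 63.5),
                               c(63.5, 63.5), c(63.5, -0.5)))
res <- analyze_ldcv_cell(movie, footprint, cohort_mean_area = 150)

res$events
#>   spot time_s        class      row      col
#> 1    4      6  full_fusion 38.96112 32.50420
#> 2    8      4 kiss_and_run 20.23055 48.88505
#> 3   10      2  full_fusion 53.31175 54.45710
```

All three scheduled events are recovered with the correct class and
frame-exact times (times are stimulus-relative seconds; positions are
0-based pixel coordinates). The per-cell summary:

```r
sprintf("vesicles: %d  events: %d  release probability: %.3f",
        res$n_vesicles, res$n_events, res$release_probability)
#> "vesicles: 10  events: 3  release probability: 0.300"
sprintf("footprint: %.1f um^2  final normalized cumulative: %.2f",
        res$footprint_area, attr(res$cumulative, "final"))
#> "footprint: 104.9 um^2  final normalized cumulative: 4.29"
```

Release probability is events over docked vesicles (3/10). The cumulative
curve is normalized to the cohort mean footprint area
(3 events × 150/104.9 ≈ 4.29 "vesicles per average cell"), which makes
cells of different sizes comparable.

The SypHy, morphometry, colocalization and calcium stages follow the same
pattern (`analyze_syphy()`, `fit_vesicle()` / `vesicle_size()`,
`manders_coefficients()` / `align_and_average_profiles()` /
`enrichment_fold()`, `calcium_image()`); the vignette in
`vignettes/vesicle-imaging-quantification.Rmd` documents the models,
assumptions and tunable parameters of each.

A thin command-line wrapper for shell pipelines is installed at
`inst/scripts/vesiquant.R`:

```sh
Rscript inst/scripts/vesiquant.R ldcv --in movie.tif --stim-onset 10 --out results/
```

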