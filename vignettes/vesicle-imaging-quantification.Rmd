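---
title: "Quantifying vesicle exocytosis from live-cell fluorescence imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle exocytosis from live-cell fluorescence imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiquant)
```

## Scope and model

Sensory neurons release two kinds of vesicle: small synaptic vesicles (SVs)
that mediate fast transmission at synapses, and large dense-core vesicles
(LDCVs) that carry neuropeptides and fuse mainly at the soma under strong
stimulation. `vesiquant` implements the quantitative image analyses used to
measure both processes in live-cell fluorescence recordings, together with a
synthetic-scene generator that produces ground-truthed inputs so that every
stage of the pipeline can be validated exactly.

The five analysis stages are:

1. **LDCV exocytosis** in TIRF movies of fluorescently tagged neuropeptide
   cargo (e.g. NPY-Venus) at the cell footprint: punctum detection, trace
   extraction, fusion-event classification, and normalized secretion
   statistics.
2. **Synaptic transmission** in synaptophysin-pHluorin (SypHy)
   epifluorescence movies: synapse identification, normalization to the
   NH~4~Cl-revealed total vesicle pool, response-time detection and
   synchrony classification.
3. **Vesicle morphometry** in super-resolution (STED) images: fitting a
   correlated elliptical Gaussian and converting its widths to physical
   size.
4. **Colocalization and synapse mapping**: Manders coefficients, selection
   of synaptic puncta by a dual-channel intensity criterion, aligned
   line-profile averaging with enrichment folds, synapse densities and
   distances to the nearest soma membrane.
5. **Ratiometric calcium**: conversion of background-subtracted Fura-2
   350/380 ratio images to nanomolar concentration.

Throughout the package, pixel coordinates are 0-based, pixel-centered and in
(row, col) order; time is expressed relative to stimulus onset (so negative
times are pre-stimulus); and intensities are arbitrary units (AU) that are
never rescaled implicitly. Those three conventions remove the most common
sources of silent off-by-one and scaling errors in image pipelines.

## Event classification rules

Fusion events are classified from fixed-position intensity traces: LDCVs at
the footprint are docked and immobile, so each detected punctum is read out
at its detection position for the whole movie as the mean intensity in a
small disk, with a local background annulus just outside the measurement
aperture subtracted frame by frame. The annulus makes the trace baseline
exactly zero after a vesicle disappears, even when pixel-level clamping of
background-subtracted frames has left a small positive noise floor.

The two event phenotypes are operationalized as follows (all thresholds are
`analysis_config()` parameters):

* **Full fusion** — the punctum disappears rapidly: the trace falls from at
  least 50% to at most 10% of its pre-event running median within 200 ms,
  and does not recover for at least 1 s. The event time is the first frame
  of the drop.
* **Kiss-and-run** — the punctum transiently brightens while releasing a
  cloud of cargo: the trace rises to at least 1.5x its running median for at
  most 0.5 s, with a concurrent spot-width increase of at least 1.3x, and
  the spot is subsequently lost. Width is estimated per frame by inverting
  the core/outer aperture flux ratio of the isotropic Gaussian spot model;
  unlike raw second moments this estimator is exact on noiseless data, free
  of patch-truncation bias, and averages pixel noise over many pixels.

The qualitative phenotypes ("rapid disappearance", "transient increase with
a cloud") require one number per clause to become testable; the numbers
above are deliberate operationalizations, are exposed in the configuration,
and are validated against simulated ground truth rather than asserted.

Each spot reports at most one event, and event candidacy additionally
requires the local running median to remain at least 30% of the spot's
initial level. Without that guard, light leaking from a neighboring event
into the aperture of an already-fused (empty) spot can masquerade as a
second event, because any excursion is large relative to a near-zero
baseline.

Secretion statistics follow the conventions of the field: the cumulative
event count of a cell is normalized to its footprint area and multiplied by
the cohort mean footprint area (so cells of different sizes are comparable
and the curve still reads in "vesicles per average cell"); release
probability is events divided by the total number of docked vesicles; a cell
is a responder if it produced at least one event.

## SypHy analysis

SypHy is quenched in the acidic vesicle lumen and fluoresces on exocytosis
or when vesicles are deprotonated with NH~4~Cl. Because reporter expression
varies from cell to cell, each synapse's trace is normalized to its own
maximum during the NH~4~Cl application (the total-pool plateau); the
normalized signal is a pool fraction and is invariant to any positive
rescaling of the raw trace, which the test suite verifies with a 10x
expression rescaling.

Synapses are identified as puncta on the NH~4~-window mean image that are
(a) immobile — centroid drift between the pre-stimulus and NH~4~ phases at
most 1 px — and (b) responsive to NH~4~Cl — window mean at least twice the
pre-application mean.

The response time of a synapse is the first time its normalized trace
exceeds the baseline mean by twice the baseline standard deviation,
sustained for two consecutive frames. The baseline window defaults to
[-10 s, -1 s] relative to stimulus onset and must precede any candidate
response; the 2-frame sustain is the minimal robustification of a criterion
that would otherwise trigger on single-frame noise, and is exposed in the
configuration. The 2xSD rule is applied to normalized traces, making it
scale-free; applying it to raw traces would make detection depend on
expression level. Responses are classified into an exhaustive four-way
partition: `pre_stimulus` (t < 0), `synchronized` (0 <= t <= 1 s; the 1-s
window reflects manual stimulus triggering and is configurable), `delayed`
(t > 1 s) and `nonresponsive`. Synchrony summaries report fractions over
responding synapses, with the nonresponsive fraction kept separate.

## Vesicle morphometry

Super-resolution vesicle patches are fitted with the correlated elliptical
Gaussian

$$f(x,y) = A\,\exp\left[-\frac{1}{2(1-cor^2)}\left(
  \left(\frac{x-x_0}{x_{width}}\right)^2 +
  \left(\frac{y-y_0}{y_{width}}\right)^2 -
  \frac{2\,cor\,(x-x_0)(y-y_0)}{x_{width}\,y_{width}}\right)\right] + offset$$

by bounded Levenberg–Marquardt least squares from a moment-based
initializer (`cor` constrained to (-0.99, 0.99), widths > 0.3 px, at most
200 iterations). Two details deserve note:

* The widths enter the exponent as Gaussian scale parameters, so the model
  value one width from the center is $A e^{-1/2} \approx 0.607A$, not half
  maximum — the customary "half width at half maximum" label for these
  parameters disagrees with the formula (a Gaussian's HWHM is
  $\sqrt{2\ln 2}\,\sigma$). The formula is authoritative here; size
  reporting keeps the customary conversion FWHM = 2 × width × pixel size so
  results remain comparable with the field's convention.
* An additive offset is included even though the pure model has none,
  because real patches sit on background and fitting without an offset
  biases widths; `fit_offset = FALSE` pins it to zero for the pure model.

Fits whose widths grow to the patch scale are flagged as unconverged: on a
pure-noise patch the optimizer happily fits a sloping plane (huge width,
compensating negative offset), and such fits must be excluded downstream.
Noiseless recovery is exact to machine precision over random parameter
draws; at a signal-to-noise ratio of 10 the median width error is about 2%.

## Colocalization and mapping

Manders coefficients are computed exactly as intensity co-occurrence sums,
$M_1 = \sum_i A_i [B_i > t_B] / \sum_i A_i [A_i > t_A]$ and symmetrically
for $M_2$, restricted to an ROI. Thresholds default to 0 on
background-subtracted images, are explicit parameters and are recorded in
the result; the test suite checks exact agreement with an exhaustive
per-pixel oracle on random images.

Synaptic puncta are selected by a dual-channel rule: both markers must
exceed the local neurite baseline by at least 1,000 AU (the baseline is the
median of the neurite ROI excluding a small disk around the punctum), with
centroids co-localizing within 2 px. The criterion is read as a per-channel
AND; reading "respective intensities" as a sum would admit puncta bright in
only one channel, which contradicts the requirement that both markers mark
the synapse.

Line profiles are sampled along 3-px-wide, ~4-µm paths at 1-px arclength
spacing with bilinear interpolation (the width is averaged along the local
normal). Profiles of each synapse are aligned on the maximum of a reference
channel before averaging — without alignment, synapse-to-synapse jitter
broadens and flattens the average peak; with it, averaging shifted copies of
one profile returns that profile undiminished. Enrichment folds divide the
mean intensity within ±0.5 µm of the aligned center by the mean in flanking
windows 0.5–1.5 µm from the center; the window sizes are configurable since
no standard exists.

## Ratiometric calcium

Ratio images are $R = (F_{350} - bg_{350})/(F_{380} - bg_{380})$, masked
where the denominator falls below a minimum; concentration follows the
ratiometric conversion $[\mathrm{Ca}^{2+}] = K_d\,\beta\,(R - R_{min}) /
(R_{max} - R)$ with an in-situ calibration (defaults $R_{max} = 3.73$,
$R_{min} = 0.64$, $K_d = 350$ nM, $\beta = 6.73$). Saturated ratios
($R \ge R_{max}$) are masked rather than capped — the conversion diverges at
$R_{max}$ and any capped value would be fabricated — while sub-$R_{min}$
ratios (noise) clamp to 0 nM with a per-pixel flag. The generator inverts
the conversion exactly, so the noiseless round trip recovers the true
calcium map to better than $10^{-9}$ nM.

## The synthetic-scene generator

`simulation_config()` fixes the study conditions the analyses assume:
immobile diffraction-limited puncta (isotropic PSF, sigma 1.3 px at 160 nm
pixels — the standard Gaussian approximation to the diffraction limit),
10 Hz acquisition, a 10 Hz pre-stimulus phase followed by a 100 Hz stimulus
phase, mono-exponential bleaching (tau 300 s), and Gaussian read noise
(SNR = amplitude / read SD) with optional Poisson shot noise. Scenes at desk
scale use 200-frame movies with a 10 s pre-stimulus phase, 10 spots in
64 × 64 px for TIRF scenes and 20 synapses in 96 × 96 px for SypHy scenes;
these sizes keep whole-suite validation fast while leaving every rule of the
analyses exercised. Spots are placed with a minimum pairwise separation of
8 PSF sigmas so that measurement apertures do not overlap — docked LDCVs and
en-passant synapses are sparse structures, and the analyses assume
resolvable puncta.

Kiss-and-run events are rendered as amplitude ×2 and width ×1.5 for 0.3 s
followed by removal; the phenotype is only described qualitatively in the
literature, so these are declared generator values, not measured claims.
Full-fusion events remove their spot instantaneously, which satisfies any
"within 200 ms" criterion.

Every generator records complete ground truth (spot positions and
amplitudes, event schedule, true model parameters, true calcium, true
Manders coefficients) before noise is applied, and a fixed seed makes output
bit-identical. What the generator does **not** emulate — and what passing
tests therefore do not establish about real recordings — includes vesicle
mobility and axial drift, fluorophore blinking, the diffusing cargo cloud
after kiss-and-run (rendered as a static widened Gaussian), spatially
structured background (cytoplasmic autofluorescence, neurites crossing the
footprint), and optics beyond an isotropic Gaussian PSF. Parameters on real
data should be reviewed against these differences, particularly the
detection threshold and the kiss-and-run width criterion.

## Numerical choices and degenerate inputs

* Background is a per-frame scalar: the mean of a user-supplied background
  ROI, otherwise the image mode. The exact integer-histogram mode is used
  when one level dominates the frame (clean or quantized data); otherwise
  the mode is the argmax of a kernel density estimate, which is stable where
  a raw histogram argmax jitters by tens of AU. Negative pixels after
  subtraction clamp to zero, preserving the non-negativity invariant of the
  movie container.
* Polygon ROI areas use the shoelace rule; rasterization includes pixels
  whose centers fall inside the polygon. Degenerate polygons (< 3 vertices,
  self-intersecting) are rejected at construction.
* Sub-pixel spot positions come from 3 × 3 quadratic interpolation of the
  band-pass response, clamped to ±0.5 px; peaks closer than 2 PSF sigmas
  merge, the brighter one winning.
* Response detection requires at least 5 baseline samples and searches only
  between the end of the baseline window and the start of the NH~4~ window,
  so the plateau itself can never register as a response.
* All random simulation is seed-scoped: generators restore the caller's RNG
  state, so interleaving simulation with user code does not silently change
  downstream draws.

## Validation strategy

The test suite is built on noiseless invertibility: every analysis stage
must recover the generator's ground truth exactly (events with
frame-accurate times and correct classes; response times and synchrony
classes; Gaussian parameters to 1e-3 relative; Manders to equality with a
brute-force per-pixel oracle; calcium to 1e-9 nM), and degrade gracefully
under noise (event recall and precision at least 0.9 at SNR 5 over 20
seeds; median width error within 5% at SNR 10). Arithmetic identities
(cohort normalization, release probability, enrichment folds, the
normalization's expression invariance) are asserted exactly.
`scripts/acceptance.R` re-runs this validation from scratch against the
installed package and writes the measured quantities as JSON.
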