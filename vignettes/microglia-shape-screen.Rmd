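---
title: "Quantifying microglial shape phenotypes in image-based siRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial shape phenotypes in image-based siRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microscreen)
```

## The problem

Microglia switch between an amoeboid (round, inflammatory-activated) and a
ramified (elongated, neuroprotective) morphology. An anti-inflammatory
stimulus such as mesenchymal-stem-cell conditioned medium drives primary
microglia toward the ramified phenotype, and an siRNA knockdown that blocks
this transition identifies a gene required for it. Because the phenotype is
purely morphological, a microscopy readout suffices: stain the cells, image
a few fields per condition, and summarize every cell outline by its
**circularity** (form factor)

$$C = \frac{4\pi A}{P^2},$$

which is 1 for a circle and decreases toward 0 for elongated or branched
outlines. A condition whose cells are *rounder* than the scrambled-siRNA
control (positive differential circularity on the log2 scale) has failed to
ramify; a condition with *lower* circularity ramified more strongly.

`microscreen` implements this entire analysis — per-cell morphometry,
screen statistics, scratch-assay migration quantification, and
delta-delta-Ct expression analysis — together with a synthetic-data module
that generates every input with known ground truth, so the pipeline is
fully testable without microscope data.

## Morphometry

Each field is processed as the original screening macro describes:

1. **Median filter**, disk footprint, radius 8 px by default (the
   protocol's value for a ×10 objective; reflective edge handling).
2. **Global automatic threshold.** The historic macro only states that a
   black-and-white image was generated; we default to Otsu's method on a
   256-bin histogram because it is parameter-free and standard for bimodal
   fluorescence fields. The method name is a config field and every
   computed threshold is logged in the run manifest, since this is one of
   the two main irreproducibility risks.
3. **Component labeling**, 8-connected (thin ramified processes stay
   attached to their somata), holes filled first so only the outer outline
   is measured, and components below `min_area_px = 50` dropped as debris
   (the protocol states no size filter; ours is explicit and configurable).
4. **Perimeter** from a sub-pixel marching-squares contour whose vertices
   are smoothed with a circular moving average (window 5 vertices) before
   the polygon length is measured. Raw pixel-edge perimeters overestimate a
   disk's boundary by ~27% (a circle would score C ≈ 0.78), and even raw
   midpoint polygons overestimate by ~5%; with smoothing a rasterized
   r = 50 px disk measures C ≈ 0.993, an equal-area square 0.80 (analytic
   π/4 ≈ 0.785), and a 2:1 ellipse 0.835 (Ramanujan-perimeter oracle
   0.841). The window was fixed once against these analytic anchors.
5. **Border exclusion**: any cell whose component touches the first/last
   row or column is excluded from quantification and retained in an audit
   table, so retained + audited always equals total.

Circularity is capped at 1, since digitization can push small round
objects slightly above the theoretical maximum.

```{r anchors}
sz <- 160
disk <- (row(matrix(0, sz, sz)) - 80)^2 + (col(matrix(0, sz, sz)) - 80)^2 <= 50^2
label_objects(disk, morph_config(min_area_px = 10))[, c("area_px", "circularity")]
```

**Scale caveat.** The median radius is a physical smoothing scale: it must
be small relative to the cell. At the protocol's magnification cells span
tens of pixels and radius 8 is mild; desk-scale synthetic images use cells
of ~8 px radius, for which the end-to-end tests scale the radius down to 3.
Filtering thin synthetic ellipses with a radius comparable to their minor
axis erodes them and biases circularity upward — a measurement property,
not a bug, and the reason absolute circularities from different
filter/magnification settings should never be compared directly (the
screen statistics only ever compare *within* an experiment against the
control).

## Screen statistics

The replication unit is the independent experiment (three in the stated
design); cells are pseudo-replicates and are pooled to one mean
circularity per (gene, siRNA, experiment) first. Within each experiment
every mean is divided by that experiment's scrambled-control mean and
log2-transformed, which removes multiplicative batch effects exactly (the
control maps to 0 by construction). The **differential circularity** of a
condition is the mean of its normalized values across experiments.

With n = 3 replicates a per-condition variance estimate is unstable, so
the default test is a **moderated one-sample t**: sample variances are
shrunk toward a prior fitted across all conditions,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  \tilde t_g = \frac{\bar y_g}{\tilde s_g/\sqrt{n_g}},\qquad
  \mathrm{df} = d_0 + d_g,$$

with \((d_0, s_0^2)\) estimated by matching moments of the log sample
variances (the empirical-Bayes scheme of the standard microarray
framework; our implementation agrees with `limma::squeezeVar` to 1e-6 and
with an independent literal transcription of the formulas to 1e-12).
When the moment system has no positive solution — the typical case when
all true variances are equal — the prior df falls back to a fixed 4, and
the fallback is recorded in the run manifest. Setting `prior_df = 0`
recovers the plain Student t exactly; zero-variance conditions are only
testable under moderation.

P-values get Benjamini–Hochberg **FDR** adjustment (implemented in the
package and checked against a brute-force two-pass oracle), and conditions
are classed `positive` (rounder than control, FDR < α = 0.05), `negative`,
or `not_significant`. Finally the off-target **validation rule**: a gene
is `validated` only when at least two of its individual siRNAs are
significant with the same sign; otherwise it is a `false_positive`.

One statistical subtlety is worth stating: because every condition in an
experiment is normalized by the same control draw, test statistics are
positively correlated *within* a run. The per-run type-I error therefore
fluctuates (we observed 0–0.30 per run at nominal 0.05) while the rate
pooled over runs is calibrated (0.049 over 30 null screens). This is an
inherent cost of negative-control normalization with a single control
well per experiment, not an implementation artifact; the FDR guarantee
over the whole screen still holds in our null simulations (≥1-hit
proportion 0.05 over 50 runs, bound 0.10).

```{r table-screen}
des <- screen_design(n_genes = 8, effect_map = c(gene002 = 2),
                     noise_sd = 0.2, seed = 1)
bundle <- run_screen(aggregated = generate_screen_tables(des))
subset(bundle$results, gene == "gene002")
bundle$validation[bundle$validation$status == "validated", ]
```

## What the synthetic data does and does not emulate

The generator is the package's stated world, with two tiers:

* **Image tier** (`generate_field`, `generate_screen_images`): dark fields
  with constant-intensity cells plus Gaussian noise. Shapes are disks,
  ellipses (aspect ratio encodes elongation) and "ramified" cells — a
  soma disk with rectangular processes attached at the chord
  \(x^\* = \sqrt{r^2 - (w/2)^2}\), which gives exact closed-form area and
  perimeter so every cell carries an analytic ground-truth circularity.
  Cells are placed without overlap (rejection sampling, 2-px separation
  halo so labeling can never merge neighbours) and a requested number of
  cells intersect the image border. Defaults: foreground 200/background 30
  on an 8-bit scale, noise SD 5.
* **Table tier** (`generate_screen_tables`): the full 157-gene × 3-siRNA ×
  3-experiment design at negligible cost; condition means are drawn as
  `control_mean * 2^(effect + eps)` with `eps ~ N(0, noise_sd)`,
  `noise_sd = 0.3` on the log2 scale and `control_mean = 0.45` (an
  elongated CM-treated baseline on the 0–1 circularity scale) by default.

Not modeled: optics (PSF, uneven illumination), staining photometry,
touching/overlapping cells, multi-channel images, time lapse. A green
image-tier test therefore establishes that segmentation and measurement
are correct for well-separated cells on a clean background — it does not
establish robustness to clumping or illumination gradients, which the
original wet-lab protocol handles by field selection.

Scratch images are a textured lawn (intensity SD 40) with a centered
low-texture vertical band; Ct tables encode a planted fold change `f` as
`base_ct - log2(f)` plus per-replicate Gaussian cycle noise.

## Scratch assay

The wound detector computes a local-variance map (15-px box window),
thresholds it with Otsu (which makes the width exactly invariant to global
intensity scaling), and keeps the largest low-variance component that
spans ≥ 80% of the image height and is solid in its bounding box (fill ≥
0.6 — percolating speckle in a fully closed lawn fails this and the image
is flagged `closed`; a uniformly blank image is flagged `degenerate`).
Width is component area divided by vertical extent — a mean width, robust
to ragged edges — plus `window - 1` px compensating the band erosion by
the variance window; synthetic bands of 150–400 px measure within ±5%.
Closure is `100 * w24/w1` and is then divided by the same experiment's
scrambled-control closure, so the control is exactly 1.0 and values < 1
mean faster closure (enhanced migration) than control.

## Expression analysis

Relative quantification uses the standard delta-delta-Ct scheme:
replicates are averaged on the Ct scale, ΔCt is taken against the
reference gene (GAPDH by default), ΔΔCt against the calibrator sample
(scrambled control), and the fold change is \(2^{-\Delta\Delta Ct}\). Any
per-sample additive Ct shift (loading differences) cancels exactly through
the reference. Although the protocol reports primer efficiencies, it uses
plain base 2; an efficiency-adjusted mode (\((1+E)^{-\Delta\Delta Ct}\)) is
available but off by default. Densitometry ratios divide each lane's
target band by its loading control and then by the calibrator lane.

## Numerical choices and degenerate inputs

* Constant images cannot be auto-thresholded: explicit error.
* Empty masks yield empty cell tables, not errors.
* A wound of width 0, or no band at all, returns width 0 with a `closed`
  flag; blank images return `degenerate`.
* Zero-variance conditions: error under Student t (with a hint), shrunk to
  a positive variance under the moderated test.
* All generators take an integer seed and restore the caller's RNG state;
  identical seeds give bit-identical outputs.
* `run_screen` contains no randomness: reruns are bit-identical, and the
  manifest records the seed, config, per-image thresholds and fitted prior.

## Known limitations

* Absolute circularities depend on the (unknowable) thresholding and
  perimeter conventions of the historic macro; only relative,
  control-normalized comparisons are meaningful.
* Touching cells are not split (no watershed); the generator never
  produces them, real data does.
* The scratch detector assumes a roughly vertical (or, with `rotate`,
  horizontal) wound spanning most of the image.
* Pixel sizes are uncalibrated (no µm conversion); all lengths are px.
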