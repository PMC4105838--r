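---
title: "Models and methods behind rootraster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rootraster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootraster)
```

rootraster quantifies root system architecture from 2-D images of roots grown
on germination paper: length, diameter, diameter-class distributions and
derived surface/volume per image. Because no imaging pipeline can be validated
against field roots whose true length is unknown, the package is built around
*artificial roots*: vectorized root systems with exactly known spline arc
length, rasterized into images that the measurement chain is then scored
against. This vignette documents the models, the tunable parameters and the
numerical choices, and states what the synthetic data do and do not establish
about real images.

## Artificial root generation

A root is an ordered list of nodes, each with a position (mm, top-left origin,
y downward — matching image row order) and a local diameter. The node polyline
is interpolated by a **natural cubic spline** parameterized by cumulative chord
length (linear for two-node roots). The spline family is a design choice: a
natural spline passes through every node, adds no overshoot at the ends, and
chord-length parameterization keeps the interpolant well-behaved for unevenly
spaced nodes. Ground-truth length is the arc length of this spline, integrated
by dense resampling; halving the resampling step (default 0.05 mm) changes the
total by less than 0.1%, so the truth is effectively step-free.

`generate_root_system()` emulates a juvenile maize system on a paper sheet:

* **Axile roots** (order 0) start near the top edge and grow as gravitropic
  random walks: per 3-mm step the heading receives Gaussian wander
  (sd 0.06 rad) and a pull of 8% of its deviation back toward vertical.
  Diameters taper linearly within 0.6–1.2 mm, the published range for maize
  axile roots on paper.
* **Lateral roots** (order 1) branch at uniform-random arc-length positions,
  at 50–80 degrees off the parent tangent, then curve downward (wander
  0.09 rad, pull 10%); lengths are 8–35 mm and diameters taper within
  0.26–0.47 mm, the published lateral-diameter range. The first node of every
  lateral lies exactly on the parent spline.

These parameter values were fixed once, on biological grounds, before any
accuracy measurement, and are not tuned.

`render()` rasterizes a system with a Gaussian cross-section whose **full
width at half maximum equals the local diameter**:
$I(p) = B + A\,\exp(-r^2/2\sigma^2)$ with $\sigma = d/(2\sqrt{2\ln 2})$, $r$
the distance to the nearest centerline sample, $B$ the paper background and
$A$ the foreground amplitude. Overlapping roots composite by **maximum** — an
opaque root lying over paper or another root — rather than by sum, which would
brighten crossings unphysically. Roots are rendered bright on dark
(the red-channel appearance of roots on blue paper); segmentation polarity
remains configurable downstream. Defaults: 0.13 mm/px (the full-slide
resolution of the reference camera setup), background 40, amplitude 180,
8-bit.

The optional **ragged-edge model** emulates the irregular root/background
boundary (root hairs, reflections) that causes thinning artefacts: the local
diameter is jittered by a Gaussian factor (sd 20% of the diameter) drawn once
per pixel of arc length and interpolated onto the dense samples. The
correlation scale matters: jitter drawn independently per sub-pixel sample is
averaged away by the max-composite and perturbs nothing, whereas pixel-scale
bumps survive rasterization and produce the expected skeleton spurs and
boundary waviness.

```{r render-example}
rs <- generate_root_system(n_axile = 2, laterals_per_cm = 1.5,
                           extent = c(60, 80), seed = 7)
rr <- render(rs, render_config())
rr$truth[1:3, ]
```

## Two-flash preprocessing

Glare from the transparent cover (droplets, folds) moves with the flash
position. The workflow therefore photographs each scene twice, lit from the
left and from the right, and combines the pair by **minimum tonal value**:
artifacts present in only one image cannot survive a pixelwise minimum, while
root shadows (cast to either side) are retained and sharpen local contrast.

Before fusion, each image is flat-field corrected. The illumination model is
**divisive** (`image / background`, rescaled to preserve the mean), because
flash vignetting is multiplicative; a subtractive model would distort the
root/background contrast ratio across the field. The background estimate is a
large-window median filter followed by Gaussian smoothing (window
`kernel_scale`, default 75 px): the median rejects thin bright roots as long
as the window is at least about five times the widest root, and the blur
removes the residual blockiness. Stage order is fixed: correct both images,
fuse, then extract the grayscale channel. Intermediate arithmetic stays in
floating point; quantization to the 8-bit range happens once per stage output.

The **red channel** is the default for grayscale conversion because blue and
grey germination papers reflect about half as much as the root between 560 and
720 nm (see the spectra section), giving the strongest contrast of the three
camera channels.

## Segmentation

Three thresholding families are provided, with polarity `root_bright` /
`root_dark` throughout and strict comparisons (a pixel equal to the threshold
is background):

* `global_threshold()` — one tonal value for the whole image;
  `auto_threshold()` selects it by exhaustive Otsu search (the published
  automatic routines of commercial packages are proprietary; Otsu is the
  standard histogram criterion and is oracle-tested against brute force).
* `adaptive_threshold()` — the image is tiled into non-overlapping square
  blocks (default 64 px); a pixel is root when it deviates from its block mean,
  in the polarity direction, by more than `proportion` (default 0.1) of the
  tonal range. The verbatim description of this rule in the root-software
  literature ("pixels with the same intensity +/- a selectable proportion")
  is self-contradictory for minority-class roots, so the polarity-signed
  deviation reading is implemented; a per-pixel moving-mean variant
  (`smooth = TRUE`) avoids block-boundary artefacts for comparison.
* `double_adaptive_threshold()` — local means over a ladder of neighborhood
  sizes (default 5, 15, 31 px); a pixel is root when its deviation exceeds
  `min_change` of the tonal range for at least one size *and* the means move
  monotonically away from the pixel value as the neighborhood grows. The
  monotonicity requirement is an addition: high-frequency paper texture makes
  the local mean fluctuate rather than drift, so it suppresses texture noise
  by construction. Interiors of regions much wider than the largest
  neighborhood see no mean change and stay background — the method is a
  band-pass detector for root-scale structures.

`clean_mask()` removes 8-connected components below a size floor and
optionally fills enclosed holes.

## Skeleton measurement

`skeletonize()` applies Zhang–Suen parallel thinning followed by a sequential
pass that deletes every remaining *simple* pixel (Yokoi connectivity number 1,
at least 2 neighbours). The second pass matters: Zhang–Suen alone leaves
two-pixel staircases on diagonal runs, and on an edge-enumerated length metric
those nearly double the measured length of a 45-degree root. The result is a
minimal 8-connected skeleton: re-thinning it is the identity.

**Length** is the chain-code metric: every unique 8-adjacent skeleton pixel
pair contributes one pixel unit orthogonally or $\sqrt 2$ diagonally. The
metric is oracle-tested against brute-force pair enumeration. Its known bias
is documented rather than hidden: a digitized straight segment at angle
$\theta$ measures $\cos\theta + (\sqrt2 - 1)\sin\theta$ per unit length, exact
at 0 and 45 degrees and up to +8% at 22.5 degrees; over the mixed orientations
of curved root systems the net effect is a low single-digit percentage,
partially offset by tip erosion during thinning.

**Pruning** (`prune()`, default 5 px in the headline pipeline) iteratively
removes terminal branches shorter than the limit that end at a junction —
thinning artefacts of ragged boundaries — while isolated paths are never
removed. The unpruned mode is retained deliberately so the artefact can be
demonstrated: on ragged-edge renders the unpruned skeleton is longer than the
pruned one and overestimates the true length.

**Diameters** come from the Euclidean distance transform of the mask:
`diameter = (2 * EDT - 1) * mm_per_px`. The half-pixel term reflects that the
object boundary lies between the last foreground and first background pixel
centre; without it a 5-px bar would measure 6 px across. Even-width bands
still digitize one pixel low in the worst phase, so diameter accuracy is one
pixel, not half a pixel. Each chain-code step is assigned to a diameter class
by the mean diameter of its two endpoints (default single edge at 0.5 mm, the
standard large-diameter axile vs small-diameter lateral split for maize);
surface and volume assume a cylinder per step.

The resolution helpers encode the detection rule of practical root imaging: a
root needs about three pixels across to be found, so at the reference setup
(490 mm imaged width, 3744 sensor pixels, hence 0.13 mm/px) the minimum
detectable diameter is 0.39 mm — within the maize lateral range, which is why
finer laterals require higher resolution.

```{r measure-example}
mask <- clean_mask(adaptive_threshold(rr$image, 64, 0.1, "root_bright"), 20)
report <- measure_mask(mask, prune_px = 5, class_edges = 0.5)
c(total = report$total_length, truth = true_length(rs)$total_mm)
```

## Spectral channel selection

Reflectance spectra are exposure-corrected
(`intensity * t_reference / t_sample`) and normalized by a white standard
(spectralon), making curves from different exposure times comparable and
dimensionless. Band contrast is the **ratio of band means** (not the mean of
pointwise ratios, which is unstable where the denominator is small), and
channel recommendation maximizes the **worst-case** $|\log$ contrast$|$ over
the supplied papers: a channel is only useful if it separates root from
background for every paper in a batch. Ties break toward the longer
wavelength. Band edges are blue 450–490, green 520–560, red 620–720 and NIR
790–1000 nm; the visible edges follow the usual camera channel ranges (only
the NIR interval is standard in the source measurements) and are configurable.

`make_fixture_spectra()` builds deterministic curves encoding the measured
qualitative relations — blue/grey papers at half the root's reflectance in
560–720 nm and above it in the NIR, white paper at twice the root throughout —
as reflectance shapes multiplied by a common lamp curve and scaled by each
measurement's exposure time, so the correction chain recovers the encoded
ratios. Absolute reflectance levels are not reproduced (they are not published
numerically); only the ratio constraints are meaningful.

```{r spectra-example}
fx <- make_fixture_spectra(seed = 1)
root_n <- normalize_to_reference(fx$root, fx$spectralon)
papers <- lapply(fx$papers[c("steel_blue", "whatman_blue", "sebio_grey")],
                 normalize_to_reference, reference = fx$spectralon)
recommend_channel(root_n, papers)$channel
```

## Evaluation

`run_benchmark()` reproduces the artificial-root accuracy experiment: ten
generated systems (2–4 axiles, 0.8–2.5 laterals/cm, drawn per system from the
run seed), rendered noiselessly at high contrast, segmented adaptively,
measured on the pruned skeleton, and scored against spline truth as absolute
per-image relative deviation. A second backend — *vector replay*, integrating
the resampled generating centerlines — measures the same images independently;
the squared Pearson correlation between the two per-image length vectors is
the cross-backend agreement statistic. Problem size: 60 x 80 mm scenes at
0.13 mm/px (615 x 462 px), ten images per run, chosen to exercise realistic
root densities while a full benchmark completes in seconds.

`repeatability()` estimates the two-way random-effects components of an
image-by-user table by method-of-moments ANOVA (expected mean squares) and
reports $R^2 = \sigma^2_{image}/(\sigma^2_{image} + \sigma^2_{error})$, with
the error term the image-by-user interaction plus residual, inseparable
without replication. Method of moments replaces the original REML fit
deliberately: for balanced complete tables the estimators have identical
expectation, in closed form and without a mixed-model dependency. Negative
moment estimates are truncated to zero; when nothing distinguishes the images
the ratio is defined as 0. Parameter recovery is verified on simulated tables
(200 images x 3 users, true ratio 0.9, recovered within 0.03).

## Numerical choices and degenerate inputs

* Threshold comparisons are strict; pixels equal to the threshold are
  background. Otsu returns `k + 0.5`, strictly between the modes.
* Double-adaptive monotonicity allows a 1e-6 tolerance so exact plateaus do
  not flip on floating-point noise.
* Empty masks skeletonize to empty skeletons (no error); constant images are
  a degenerate-input error for `auto_threshold()`.
* `prune(s, 0)` is the identity; after each spur-removal pass the skeleton is
  re-thinned, dissolving one-pixel stubs left where a spur attached
  diagonally.
* Variance components are truncated at zero; zero-variance backends are an
  error for `pairwise_r2()` rather than a silent `NA`.
* All randomness (generation, noise, ragged edges, fixtures) is seeded;
  `render()` defaults to the system's own seed, so a system renders
  identically wherever it is rendered.

## What the synthetic data do and do not show

The generator produces smooth, well-separated, noiseless-to-mildly-noisy roots
with exactly known truth. Passing the accuracy bounds on these images
establishes that the segmentation-thinning-measurement chain is sound — the
same conclusion the artificial-root experiment supports for commercial
packages — but **not** that real rhizoslide images will measure to 5%: real
paper adds texture noise, moisture gradients, root hairs and crossings whose
ground truth is unknown, and published cross-software correlations drop
sharply from artificial to real images. Known limitations within the
synthetic domain: very dense systems underestimate slightly because masks of
touching roots merge at junctions (the skeleton takes shortcuts), the
chain-code metric overestimates straight oblique segments by up to 8%, and
diameters are only pixel-accurate. Root-order topology (assigning skeleton
branches to individual roots), time-series tracking and human-interactive
tracing are out of scope.
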