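---
title: "Finite-difference PD saliency probing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-difference PD saliency probing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdprobe)
```

## The problem and the method

Deep regression models that read a hand radiograph and return a bone age
(in months) are accurate but opaque. `pdprobe` interrogates such a model
*without any access to its weights*: it treats the model as a black-box
function $f$ from a packed $299 \times 299 \times 3$ integer image $x$ to a
scalar age, and estimates the partial derivative of the prediction with
respect to each pixel's intensity by a forward finite difference. For
pixel $p$, all three channels are incremented together by a step $h$
(default $h = 1$ intensity unit, the smallest move on the integer scale):

$$\mathrm{PD}(p) \;=\; \frac{f(x + h\,e_p) - f(x)}{h},
\qquad e_p = \text{unit increment of all 3 channels of } p .$$

The unit is months per intensity unit. Repeating this at every pixel of a
region (usually the hand mask) yields a *PD map* — a saliency map that
needs only forward evaluations of the model. Because the difference
quotient is exact for affine models and biased by at most
$\tfrac{1}{2} h\,B$ for models with second derivative bounded by $B$ along
the probe direction, the probe can be validated rigorously against
closed-form surrogate regressors shipped with the package.

Downstream, absolute PDs (APDs) are averaged over five anatomical regions
of interest (wrist; mid-metacarpal sections; metacarpal–phalanx joints;
fingers; the thumb-web muscle area), each image's ROI means are divided by
the sum over ROIs 1–4 to give *relative mean APDs* on a per-image scale,
and those are regressed against the reference age to test whether a
region's influence on the prediction is age dependent. ROI 5 is divided
by the same ROI 1–4 denominator: its relative values then live on the
shared scale of the bone-bearing regions, which is what makes a regression
intercept near 0.4 for a muscle region interpretable at all. The
alternative (normalizing over all five ROIs) would force the five values
to sum to one and make ROI 5's trend an artefact of the others; the shared
denominator is therefore the default and the `norm_set` argument makes the
choice explicit.

## Image preparation

The preparation chain mirrors standard practice for hand-radiograph
models:

1. **Background subtraction** (`subtract_background`): the background
   level is estimated as the 1st-percentile intensity by default (a robust
   stand-in for the dark border of a radiograph); a fixed level can be
   given instead. Output is clipped at zero.
2. **Hand mask** (`generate_mask`): Otsu threshold by default (no fixed
   threshold generalizes across exposures), then a morphological opening —
   erosion followed by dilation with a disc of radius 5 at the 598-pixel
   scale — to delete small isolated bright islands, then retention of the
   largest connected component. Radius 5 removes anything thinner than 11
   pixels while leaving fingers (about 20 pixels wide after resizing)
   intact. Manually traced masks can be supplied as files and bypass this
   step.
3. **Masking** (`apply_mask`): intensities outside the hand are set to
   exactly zero, so the model never sees background structure.
4. **Square crop and resize** (`crop_square_resize`): the mask's bounding
   box, optionally expanded by `margin_frac`, is made square (zero-padded
   where it leaves the frame) and resized bilinearly to
   $598 \times 598$. The mask is transformed identically and re-binarized
   at 0.5; label maps travel with nearest-neighbour resampling so labels
   are never invented by interpolation.
5. **Cell packing** (`pack_cells`): the image is divided into
   $299 \times 299$ cells of $2 \times 2$ pixels. In each cell the bottom
   two pixels fill channels 1 and 2 (left to right) and the mean of the
   top two fills channel 3. The rule is lossless for the bottom row and
   the top-row mean. Left-to-right order within the bottom row is a fixed
   convention; the probe increments all three channels together, so any
   fixed order yields the same PD map.
6. **Intensity scaling** (`rescale_to_254`): the whole frame's range is
   mapped affinely to integers 0–254 with half-up rounding. Scaling over
   the whole frame rather than inside the mask is deliberate: after
   masking the background is exactly zero, so the frame minimum is 0 and
   the two conventions coincide on masked images. The 0–254 ceiling
   leaves headroom so the $+1$ probe (max 255) stays inside the 8-bit
   range any model input pipeline must accept.

The whole chain is deterministic; identical inputs and configuration give
bit-identical packed images.

The model operates on the 299 grid, while masks live on the 598 grid; a
mask is reduced by majority vote over each $2 \times 2$ cell, with ties
counted as inside (the least biased fixed rule — a strict-majority rule
would systematically shrink the hand). Label maps reduce the same way,
with ties between ROI labels going to the smaller label and the
"unassigned" label winning only on strict majority.

## Surrogate regressors and what they certify

`make_surrogate` ships five closed-form models used as oracles:
constant, linear, quadratic, a smooth bounded "radial bump" of weighted
pixel sums, and a regional-sum model driven by a label map. Each carries
its analytic gradient (`analytic_gradient`) and a documented curvature
bound $B$ along the probe direction, so two properties can be asserted
exactly:

* **Affine exactness** — for the linear surrogate the PD map must equal
  the channel-summed weight grid *bitwise*. To make that meaningful in
  floating point, the default linear weights are dyadic rationals
  (integer multiples of $2^{-30}$, uniform on about $[-10^{-4}, 10^{-4}]$):
  every product with an integer intensity and every partial sum is then
  exactly representable in double precision, and the forward difference
  carries no rounding error at all. The magnitude puts per-pixel PDs in
  the $10^{-3}$–$10^{-2}$ range typical of hand-mask probes, so rendered
  overlays exercise the same display range as real maps.
* **Curvature-bounded accuracy** — for twice-differentiable surrogates
  the probe must match the analytic directional derivative within
  $\tfrac{1}{2} h B$. For the radial bump,
  $B = 9\,w_{\max}^2\,A\,\frac{4}{3\sqrt 3}/\sigma^2$ follows from the
  chain rule ($u$ moves by $3 w_p$ per unit step and
  $|\tanh''| \le 4/(3\sqrt 3)$).

Stochastic models are outside the regressor contract: `predict` must be
deterministic, and callers wrap sampling-based models in a fixed inference
mode before probing. The baseline prediction is computed once per map and
reused — under the determinism contract this is indistinguishable from
recomputing it per pixel, and halves the model calls.

## The phantom generator

`make_phantom` draws a geometric hand: a wrist block, a palm ellipse, four
finger capsules and a slanted thumb, all bright on a dark background, with
bone-like cores whose width (1–4 px half-width) and contrast (30–90
intensity units) increase monotonically with the `age_months` parameter
over the 15–216 month design range — the age range the probe's regression
stage is meant to span. Defaults: 598-pixel frame, background level 10,
foreground 140, Gaussian noise SD 2, and three isolated bright islands of
radius 3 placed in the strip above the hand. The noise and island levels
are mild by design: they exercise thresholding and island cleanup without
ever threatening the Otsu separation, which is what a well-exposed
radiograph also looks like after background subtraction.

One construction detail is load-bearing: the silhouette is generated as
the *dilation* of a skeleton by the same disc brush that `generate_mask`
uses for its opening. Opening is an identity on any set that is a
dilation by the same structuring element, so on a noise-free phantom the
default mask pipeline must recover the ground-truth mask *pixel for
pixel* — an exact oracle that would be unattainable with, say, a plain
rectangle, whose corners a disc opening rounds off.

The five ground-truth ROI label regions follow the anatomical roles
(wrist; five disconnected mid-metacarpal bands; five joint patches;
fingers; a small thumb-web patch, the smallest region). They are assigned
in priority order so labels are disjoint, and the bundle's declared pixel
counts are the actual counts.

What phantoms do *not* model: ossification centres, growth-plate fusion,
soft-tissue gradients, exposure variation, or anatomic variability —
passing tests certify the probe, statistics and plumbing, not clinical
performance on radiographs. Cohorts (`make_cohort`) draw ages uniformly on
[15, 216] months under one master seed, with per-phantom sub-seeds so
interleaved generation never couples streams.

Note one consequence of the geometric design: phantom geometry is
identical across ages (only core intensity changes), so an *affine*
surrogate — whose PD map is independent of the image — produces identical
relative mean APDs for every phantom. End-to-end runs with the linear
surrogate therefore test determinism and plumbing, not trend recovery;
trend recovery is certified separately on synthetic (age, value) data with
known slope and noise.

## Numerical and design choices

* **Forward difference, $+1$, all three channels** is the probe's
  definition, not an approximation choice; a central-difference mode
  exists behind `mode = "central"` for callers who want the smaller bias
  at twice the cost, and is off by default.
* **Rounding** in `rescale_to_254` is half-up (`floor(x + 0.5)`), chosen
  over R's round-half-to-even so the map is monotone in the input with no
  parity artefacts.
* **Display transform**: scores are `tanh(pd / T)` with the display
  threshold $T$ as the natural scale ($T$ maps to $\tanh 1 \approx 0.76$,
  $\pm\infty$ to the colormap extremes). Defaults: $T = 4\times10^{-3}$
  inside the mask and $4\times10^{-2}$ for outside-mask maps, which run
  about an order of magnitude hotter. A hard clamp is available via
  `clamp = TRUE` for readers who prefer threshold saturation. Beyond
  roughly $19\,T$ the tanh is indistinguishable from $\pm 1$ in double
  precision; monotonicity is therefore only numerically meaningful inside
  that range. The diverging blue–white–red map is midpoint-symmetric, so
  negating a PD map exactly swaps the red and blue channels.
* **Degenerate inputs** fail loudly: constant images cannot be
  thresholded or rescaled; empty masks, empty probe regions, non-finite
  predictions and zero normalization denominators are errors, not
  warnings. Exact regression fits (slope recovered with zero residual, as
  with affine surrogates) are accepted silently.
* **Statistics**: ordinary least squares with the classical two-sided
  t-test on the slope (`stats::lm`), sample SD with the $n-1$ denominator
  in cohort tables, and no multiple-testing correction across ROIs —
  per-ROI p-values are reported as-is.
* **Pixels labeled but not probed** (possible at the edge of the mask
  reduction) are excluded from ROI means and counted in the
  `excluded_px` column rather than silently imputed.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
phantom fixtures at the native 598/299 scales: full-hand-mask probe maps
(about 26 000 pixels), a $32 \times 32$ curvature-bound region, a
20-phantom cohort probed over all labeled pixels (about 13 000 per image)
for the normalization and cohort statistics, 500 seeded replicates of the
slope-recovery study ($n = 100$ images each), and a five-phantom
end-to-end pipeline run executed twice to verify bit-identical outputs.
These sizes were chosen so the full certification runs comfortably on a
single CPU while still exercising every code path at the model's true
input resolution.

## Limitations

* The probe costs one model call per pixel; `batch_pd_map` exists so
  vectorized models can amortize that, and is verified bit-identical to
  the sequential path.
* Orientation normalization of real radiographs (straightening, left/right
  hand) is the caller's responsibility; only a horizontal-flip flag is
  offered.
* ROI label maps for real images must be supplied by the user (drawn
  manually or by other tools); automatic anatomy segmentation is a
  non-goal, and the generator labels only phantoms.
* Relative mean APDs are per-image ratios: they remove each image's
  overall sensitivity scale, which is the point, but it means cohort
  comparisons of *absolute* sensitivity must use `mean_apd` instead.
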