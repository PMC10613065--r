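---
title: "Backlight grain phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backlight grain phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscan)
```

## The measurement problem

Rice breeding programs score panicles by their total grain count, the
number of *filled* grains (grains with a developed endosperm), and grain
dimensions. Under backlight — a light panel behind a glass stage, camera
above — a filled grain is largely opaque and casts a dark silhouette,
while an unfilled grain transmits light through its empty hull and
appears as a bright interior inside a darker outline. grainscan turns
one such 8-bit grayscale image into per-grain phenotypes and per-panicle
counts.

The pipeline is fixed: line-scan restoration (when the image comes from
a rotating stage), median filter, fixed-threshold binarization,
morphological closing, small-object removal, marker-based watershed,
then per-grain classification and measurement.

## Line-scan restoration

A line-scan camera over a turntable records one radial pixel row per
encoder pulse. A point at source coordinates $(u, v)$ (radial position,
scan-line index) corresponds to the planar position

$$\rho = e^{u \ln(w)/w}, \qquad \theta = \frac{2\pi v}{S}, \qquad
  x = w + \rho\cos\theta, \qquad y = w + \rho\sin\theta,$$

where $w$ is the source width in pixels and $S$ the number of scan
lines per revolution. The natural logarithm is the only base for which
$u = w$ maps to $\rho = w$, so $\rho$ spans exactly $[1, w]$ and the
restored raster is $(2w+1)$ pixels square. $S$ defaults to $w$ but is a
separate parameter: a capture need not contain exactly $w$ lines per
revolution. Multi-revolution stitching is out of scope.

Resampling runs through the analytic inverse: each destination pixel
inside the annulus pulls its value from the source at
$u = w\ln(\rho)/\ln(w)$, $v = S\theta/2\pi$, with bilinear interpolation
by default. Inverse mapping avoids the holes and aliasing a forward
splat would produce. Interpolation wraps cyclically across the $v = 0$
seam; the disc $\rho < 1$ at the turntable axis is undefined and takes
the configured fill value. Coordinates are 0-based $(column, row)$ with
the origin at the top-left and $\theta$ counterclockwise in image axes.

The magnification of this map is radius-dependent: a source column
spacing of one pixel corresponds to $\rho\ln(w)/w$ planar pixels at
radius $\rho$. Content near the rim is therefore under-sampled in the
raw capture, and a faithful round trip (distort, then restore) is only
possible for grains within roughly $0.8\,w/\ln w$ of the axis. The
round-trip tests place their grains inside that band — a property of
the imaging geometry, not of the implementation.

## Preprocessing

Four stages, in a fixed order, each preserving the raster shape:

* **Median filter**, 5×5 by default, with replicate padding at the
  borders (constant padding would darken the border and create false
  foreground). Removes sensor noise and debris specks smaller than the
  window.
* **Binarization** at a fixed grayscale cut, default 220. The backlight
  background is near-saturated (about 235) while even translucent
  unfilled interiors stay below about 215, so a single cut just below
  saturation separates foreground from background; the rig's
  illumination is assumed uniform, so no local thresholding is offered.
  An Otsu fallback can be switched on for convenience; it is off by
  default and inappropriate for scenes dominated by translucent grains,
  whose bright interiors end up above the bimodal cut.
* **Morphological closing** with a 5 px disc. The glume gap — the
  opening between the grain shell and its empty glume — transmits light
  and punches a 1–3 px hole in the mask; a 5 px element fills such
  holes without bridging grains 8 px apart. The result is forced to be
  a superset of its input so closing can never erode a grain clipped by
  the raster edge.
* **Small-object removal** drops 8-connected components under
  500 px². A grain at 0.086 mm/px occupies roughly 3,000 px², so the
  default cut rejects clastic debris with a 6× margin.

Binarization is threshold-monotone (raising the cut never removes
foreground), closing only adds foreground, and removal only deletes
whole components — properties the test suite asserts directly.

## Watershed segmentation

Grains on the stage touch. Markers come from the Euclidean distance
transform of the cleaned mask: *sure foreground* is the set of pixels
whose distance to background is at least a fraction of the distance
maximum, taken per 8-connected component by default (a global fraction
starves small grains next to large ones); the *sure background* bound
is the mask dilated three times with a 3×3 box; the band between them
is the *unknown* region. Each sure-foreground component seeds one
grain; flooding runs on the inverted distance transform, because
backlight grains are near-uniformly dark inside clumps and the
intensity gradient carries no boundary information there. Flooding is
restricted to the mask, so the number of final grain labels always
equals the number of seeds, every mask pixel is assigned, and labels
form connected regions. The flooding itself is EBImage's deterministic
`propagate`; ridge ties are resolved by its internal order, which is
stable across runs.

The sure-foreground fraction defaults to **0.55**. The choice is the
one genuinely delicate constant in the pipeline, and it is set by a
geometric trade-off. When two grains touch, binarization edge spread
(the fixed threshold sits high on the grain-to-background edge ramp)
and the closing element weld the silhouettes together over a contact
band; the distance transform inside that band reaches roughly a third
to a half of the grain half-width. A fraction of 0.4 leaves the two
cores connected through the weld for a substantial share of contacts;
0.55 separates them while an isolated elliptical grain — whose medial
ridge declines smoothly toward the tips — still yields a single
connected core. The test suite verifies both sides of the trade-off:
separated scenes count exactly (no over-segmentation), and scenes with
30% of grains in touching pairs stay within a 2% counting error.

One guard accompanies the threshold: sure-foreground components smaller
than `min_seed_area` (10 px by default) are dissolved back into the
unknown region instead of seeding a grain. The discrete distance
transform zig-zags by a fraction of a pixel along diagonal medial
ridges, so an isolated pixel can cross the per-component threshold on
its own and would otherwise flood a phantom region; a genuine grain
core at these scales is hundreds of pixels.

Grains touching the raster border are excluded by default (and
counted): a clipped grain would bias both size and dark-ratio
statistics.

## Filled/unfilled classification

Each grain's pixel grays are split into two clusters. One-dimensional
$k$-means has a globally optimal solution at a contiguous split of the
sorted values, so the package scans all $n-1$ split points with prefix
sums and returns the exact optimum — no random starts, no convergence
tolerance, fully deterministic. The cluster with the lower centroid is
"dark". The **dark ratio** is

$$DR = N_d / N_t,$$

the dark-pixel fraction of the grain, and a grain is *filled* iff its
dark ratio strictly exceeds the threshold, default **0.6** (a value
exactly at the threshold is unfilled). Reference class means are 0.87
for filled and 0.25 for unfilled grains, so the default threshold sits
between the classes; it is exposed because rice variety, grain cracks
and backlight intensity all shift the distributions.

Grains whose gray span is at most 2 levels have no two-cluster
structure; such degenerate grains take $DR = 1$ when their mean gray is
below half the binarization threshold (an opaque uniform grain) and
$DR = 0$ otherwise.

## Size measurement

Length and width come from the minimum-area enclosing rectangle of the
grain's pixel set — rotating calipers over the convex hull, one
candidate orientation per hull edge — multiplied by the resolution
(0.086 mm/px by default). Sides are measured as the span between
outermost pixel *centers*, with no +1 footprint correction: the fixed
binarization threshold already captures partially covered boundary
pixels (it sits at roughly 10% edge coverage for an opaque grain), so
the center span is the less biased estimate of the true silhouette
extent. On synthetic grains with antialiased edges the combination
lands within ±2 px on both axes. The rectangle angle is reported in
degrees, long side, in $[0°, 180°)$.

## Evaluation statistics

Predicted values $m_j$ are compared with actual values $e_j$ by

$$R^2 = 1 - \frac{\sum_j (m_j - e_j)^2}{\sum_j (m_j - \bar m)^2},
\qquad RMSE = \sqrt{\tfrac1n \sum_j (m_j - e_j)^2}, \qquad
MAPE = \tfrac1n \sum_j \frac{|e_j - m_j|}{m_j}.$$

Two details are nonstandard and deliberate: the $R^2$ denominator is
centered on the *predicted* mean, and the MAPE denominator is the
*predicted* value. These are the printed forms of the statistics this
package reproduces, and they are implemented exactly as printed; the
conventional forms (both denominators from the actuals) are available
via `standard = TRUE` for comparison. For near-perfect predictions the
two versions are numerically close. MAPE is stored as a fraction and
reported ×100 as percent. Constant predictions leave the $R^2$
denominator empty; `r_squared()` raises an error and
`threshold_sweep()` records `NA` for that threshold.

`threshold_sweep()` re-classifies every grain at each candidate
dark-ratio threshold, counts filled grains per panicle, and scores the
counts. Thresholds below the optimum absorb dark-leaning unfilled
grains (overestimation); thresholds above it spill filled grains into
the unfilled class (underestimation). On synthetic panicles the sweep
over {0.4, 0.6, 0.7, 0.8} peaks (maximal $R^2$, minimal RMSE) at 0.6
with exactly those error directions on either side.

## The synthetic scene generator

No public backlight rice dataset accompanies the method, so the
package's validation substrate is a generator with exact ground truth.
What it emulates, and what it deliberately does not:

* **Geometry.** Grains are rotated ellipses with lengths uniform in
  8.0–11.0 mm and widths in 2.0–3.0 mm at 0.086 mm/px — the size range
  of mature indica rice on this kind of rig. Edges are rendered at 4×
  supersampling and box-downsampled, so sub-pixel coverage is correct
  and ±2 px size-recovery tests are meaningful.
* **Appearance.** Background gray 235 with Gaussian noise (sd 3).
  Within each grain a contiguous dark region grown from one end
  (emulating endosperm fill) covers exactly the grain's target dark
  fraction, the remainder taking light grays; unfilled grains carry a
  3.5 px dark outline ring, the silhouette of the hull. The ring width
  matters: a ring much thinner than the 5×5 median window is erased by
  the filter and the measured dark ratio collapses; at 3.5 px the
  rendered per-grain dark fractions stay within ±0.05 of target.
* **Class dark fractions.** Truncated normals with means 0.87 (filled,
  range 0.55–0.98) and 0.25 (unfilled, range 0.12–0.50), sd 0.08 for
  both. The means are the reference class averages. The spread is a
  free design choice set from a tail-mass calculation: with sd 0.08,
  a few percent of unfilled grains exceed dark ratio 0.4 and a few
  percent of filled grains fall below 0.7, while essentially no mass of
  either class crosses 0.6 — the regime in which the threshold sweep
  shows its characteristic over/under-estimation pattern yet 0.6 stays
  near-perfect. (With sd 0.05 misclassification at *any* of the swept
  thresholds becomes a once-per-thousand-grains event and the sweep
  degenerates.) The unfilled lower bound 0.12 reflects that the
  outline ring alone contributes about that fraction.
* **Clutter.** Optional 1–3 px bright glume-gap holes inside grains
  (closed by preprocessing) and 15 dark debris specks of 2–8 px
  (removed by the area cut).
* **Placement.** A jittered grid guarantees a minimum clearance of
  8 px in `separated` mode. `touching_pairs` and `mixed` modes place
  tangent pairs with a −1..0 px gap. Pair contacts are **tip-to-tip
  with angular scatter**, enforced by resampling until the 1 px-inflated
  contact-lens area is at most 14 px²: flank-to-flank contact of two
  2-D ellipses generically *osculates* — the boundary curvatures match
  and the silhouettes run sub-pixel-close over tens of pixels — welding
  them into a single blob that no segmentation method could split.
  Real convex 3-D grains meet at point contacts and do not exhibit
  this; the rejection rule removes the 2-D artifact rather than making
  the task artificially easy.
* **Intensity.** A multiplicative brightness factor emulates backlight
  intensity changes: mean scene gray increases strictly with it. This
  reproduces the qualitative brightness trend only; the physical
  saturation and contour-loss effects of severe overexposure are not
  modeled.

What passing tests on this substrate do **not** show: robustness to
non-elliptical grain shapes, awns and attached glumes, cracks in
covering layers, rice-blast black spots on unfilled grains (a known
over-prediction source, not modeled), uneven illumination, or clumps
three and more grains deep. Accuracy numbers on synthetic scenes bound
the algorithmic error of the pipeline, not its field performance.

Scenes are bit-identical under a fixed seed; the analysis pipeline
itself has no stochastic stage (the clustering is exact), so the whole
path from seed to CSV is reproducible.

## Problem sizes used in the checks

The test suite validates counting on 20 separated and 20 mixed scenes
of 130–290 grains (the per-panicle totals a rice spike typically
bears), classification on 30 scenes with class dark fractions
conditioned to [0.75, 0.95] and [0.15, 0.35], the threshold sweep on 15
panicles, size recovery on 200 grains, and the restoration round trip
on a $w = 1600$ turntable frame. The acceptance script recomputes the
same quantities on 8–15 scenes per experiment. Oracle checks (median
filter, distance transform, exact 2-means, the three statistics) run
against brute-force reimplementations at small sizes where exhaustive
computation is cheap.

## Numerical and degenerate-input conventions

* Ties in the 2-means split scan resolve to the first minimal split;
  equal-cost partitions are equivalent in dark ratio.
* A dark ratio exactly at the threshold is unfilled ("exceeds" is
  strict).
* Regions under 3 px cannot support a rectangle and raise a
  degenerate-region error; empty masks yield zero seeds, not an error;
  an empty phenotype table summarizes to zero counts with an undefined
  filled fraction.
* The out-of-annulus condition from the inverse map is a distinct
  condition class, so resampling can substitute the fill value without
  masking genuine errors.
* Grayscale I/O is 8-bit; restored images are rounded to integer
  levels.
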