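---
title: "Live-wire OCT segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Live-wire OCT segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlivewire)
```

This vignette documents the science and the engineering decisions behind
`octlivewire`: the graph model, the boundary-specific preprocessing, the
peripapillary and fluid pipelines, the evaluation metrics, what the phantom
generator does and does not emulate, and the numerical conventions that make
every run bit-reproducible.

## The graph model

A B-scan is a matrix of reflectivities in $[0,1]$ with rows indexing depth
$z$ (growing toward the choroid) and columns the lateral position $x$.
Segmentation operates on an 8-connected, undirected pixel graph. Given a
strictly positive per-pixel cost $c$, the edge between neighbours $a$ and
$b$ weighs

$$w(a,b) = \frac{c(a)+c(b)}{2}\cdot\begin{cases}\sqrt 2 & \text{diagonal}\\
1 & \text{axial}\end{cases},$$

so a uniform-cost image yields Euclidean path lengths and the tracer has no
directional bias. A boundary is traced as the concatenation of Dijkstra
shortest-path-first runs between consecutive user anchors; the pixel path is
collapsed to one depth per column by averaging the visited $z$ in each
column, and anchor columns are pinned to the clicked depth. No monotonicity
constraint is imposed in the graph itself — monotone $x$ is required only of
the anchor sequence — so locally steep boundary stretches remain traceable.

Assumptions: the target interface is, within its search region, the cheapest
ridge of the cost image; and clicks are close enough together that the
cheapest path between them does not find a shortcut through another
interface. The region-of-interest (ROI) machinery below exists precisely to
make the first assumption true per boundary.

## Boundary-specific cost images

Each of the nine interfaces (ILM through the outer RPE boundary) gets its
own background via the chain

denoise → polarity-rectified vertical gradient → morphological clean →
gamma contrast → ROI mask → cost $=(1-\text{edge})+\varepsilon$.

The tunable parameters, all per-boundary and overridable through a JSON
config:

| parameter | default | unit | role |
|---|---|---|---|
| `gaussian_sigma` | 1.5 | px | speckle suppression before differentiation; ~6 µm at a 3.9 µm axial pitch |
| `polarity` | per label | — | keeps only the gradient sign that characterizes the interface |
| `morph_radius` | 2 | px | half-length of the horizontal line element; closing bridges ≤ 2·radius gaps along a ridge, opening removes isolated speckle responses |
| `contrast_gamma` | 1.0 | — | optional edge-map contrast shaping |
| `roi_above`, `roi_below` | per label | px offsets | restrict the edge map to the band between already-traced neighbours |

The default polarity table follows the qualitative reflectivity ordering of
the retinal bands (vitreous dark, NFL bright, GCL darker, IPL brighter, INL
dark, OPL bright, ONL darkest, photoreceptor/IS-OS and RPE brightest,
choroid intermediate): ILM, GCL–IPL, INL–OPL, ONL–PR and PR–RPE are
dark-to-light; NFL–GCL, IPL–INL, OPL–ONL and the outer RPE boundary are
light-to-dark.

**Sequential order.** Boundaries are traced strongest-first, each
ROI-restricted by its already-found neighbours: ILM, outer RPE, ONL–PR,
PR–RPE, IPL–INL, OPL–ONL, INL–OPL, NFL–GCL, GCL–IPL. Tracing ONL–PR before
PR–RPE matters: the ONL→photoreceptor step is by far the strongest
dark-to-light edge in the outer retina, and because the gradient map is
normalized globally, the much weaker PR–RPE edge is only the cheapest ridge
of *its* cost image once the ONL–PR edge has been excluded from its ROI
(offset 6 px above, versus the 2 px used elsewhere, so the smoothed tail of
the strong edge cannot leak in). When only a subset of boundaries is
requested, ROI references to untraced labels are dropped rather than
erroring — the search band around the anchors then provides the
localization.

## Tracing mechanics and numerical conventions

* **Cost floor** $\varepsilon = 10^{-6}$, added when every cost image is
  built: forbids zero-cost cycles and keeps Dijkstra's optimality
  assumptions intact.
* **Determinism.** The priority queue breaks equal distances by smaller
  $(z, x)$; predecessors update only on strict improvement. Identical
  inputs therefore give bit-identical paths, which the suite verifies at
  the level of output file bytes.
* **Search band.** Each anchor-to-anchor run is restricted to the rows
  spanned by the two anchors padded by 40 px (configurable), the full span
  in $x$. This reflects the local nature of clicks and keeps a 496 × 512
  trace with 5–9 anchors well under a second.
* **Sub-pixel depths.** Boundaries store real-valued $z$ (column averaging
  and grader averaging produce fractions); rasterization for overlays
  rounds half-up. CSV output carries 6 decimals, making the roundtrip
  lossless to $5\times10^{-7}$ px.
* **Local correction** re-traces only the interval spanned by the
  correction anchors and imposes no smoothing at the seams — the clicked
  endpoints are authoritative, exactly as in interactive use.

## Grid fallback

The grid tool places $n$ vertical lines (first at
$\lfloor w/2n\rfloor$, spacing $\lfloor w/n\rfloor$), takes one click per
line and interpolates with a shape-preserving monotone cubic
(Fritsch–Carlson slopes), extended to the image edges linearly with the
outermost secant slope. Monotone interpolation was chosen over a natural
spline deliberately: at the foveal pit a natural spline rings and
overshoots, which is clinically misleading. The price is accuracy at
under-sampled extrema — any no-overshoot interpolant is clamped to the data
range between consecutive clicks, so a 10 px amplitude sine sampled every
~51 px cannot be recovered better than ~3 px at its crests regardless of
method. The tests assert exactly that bound, and that doubling the click
density brings the whole curve within 1.5 px. R's `splinefun(method =
"monoH.FC")` was found to overshoot badly on non-monotone data (tens of
pixels on random click sets), so the implementation uses `signal::pchip`,
which the suite property-checks for the no-overshoot invariant.

## Peripapillary pipeline

1. **Reference boundary.** The flattening reference is estimated as the
   per-column argmax of a 5 px vertical moving average restricted to the
   lower 60% of rows (the hyperreflective photoreceptor–RPE complex),
   median-filtered with width 15; ties take the smaller depth. Any
   consistent bright-band tracker suffices here: the shift vector only
   needs the *shape* of the curvature, and the estimate is never reported
   as an anatomical boundary.
2. **Shift vector.** $s_x = \mathrm{round}(\max_x z_{\mathrm{ref}} -
   z_{\mathrm{ref}}(x))$; all entries non-negative with at least one zero.
3. **Flattening** circularly shifts each column down by $s_x$; the inverse
   shifts up, and the roundtrip is exact at bit level. Rows wrapped in from
   the bottom sit above the retina and are excluded from vessel profiling.
4. **Vessel shadows.** The mean intensity of each column from IPL–INL to
   the bottom of the flattened scan forms a lateral profile; after a
   width-5 moving average, vessels are its local minima with prominence
   ≥ 0.05 (intensity units). The reported centre is the midpoint of the
   half-prominence interval — markedly more noise-robust than the argmin,
   which wanders across the flat bottom of a shadow dip — and the
   half-width is half that interval, capped at 15 px. Because the paper's
   pipeline needs IPL–INL before that boundary has been traced, a
   provisional curve is interpolated from the IPL–INL anchors (or, absent
   those, the flattened reference) purely for profiling.
5. **Removal** replaces the left half of each shadow with the columns
   immediately left of the interval and the right half with those
   immediately right; edge-touching vessels degrade to a one-sided copy
   with a warning. Non-vessel columns are untouched at bit level.
6. **Tracing and unflattening.** Eight boundaries (GCL–IPL is excluded in
   this mode) are traced on the repaired flat image with the same
   machinery, then mapped back by subtracting $s_x$; a trace that would
   wrap past the image raises an error naming the columns.

## Fluid pipeline

The fluid background is Canny edges (σ = 2, hysteresis thresholds 0.1/0.3
on the max-normalized gradient magnitude — no installed R package provides
Canny, so the detector, including non-maximum suppression and 8-connected
hysteresis, is implemented here), closed with a disk of radius 2 to bridge
broken rims, then softened into a graded map decaying by 0.5 per pixel of
distance from the nearest edge. Closed contours run anchor-to-anchor plus a
closing segment; self-touching loops are pruned so the cycle is simple.
Rasterization fills everything not 4-connected to the image border through
the contour — equivalent to even-odd filling for simple contours and
well-defined for any pruned cycle. Components are labelled 8-connected;
`filter_small_objects` drops components under `min_area` (default 50 px,
configurable — the threshold that removes "marginally small" objects is a
convention, not a measurement). Dice between empty masks is defined as 1,
empty-versus-non-empty as 0, so the metric is total.

## Metrics

Unsigned error is computed over the columns where both curves are defined,
with $w$ equal to the size of that common range, so partial traces remain
comparable. The irregularity index is reported exactly as the
chord-to-arc ratio $L_r/L_b$ (1 for any straight boundary, smaller for
deformed ones); because the name suggests the reciprocal to some readers,
an `inverse` flag offers $L_b/L_r$. Bland–Altman reports bias, $\pm1.96$ sd
limits (sd with denominator $n-1$) and the percentage of differences inside
the limits; for normally distributed differences this calibrates to ~95%,
which the suite checks on $10^4$ seeded draws. `pct_within` is reported as
defined here without claiming equivalence to any published "total
agreement" figure.

## The phantom generator

Phantoms emulate: ten reflectivity bands in the standard ordering, smooth
curvilinear boundaries with at least 2 px separation everywhere (violations
abort before rendering), sub-pixel band edges via linear partial-volume
blending, a Gaussian foveal pit depressing inner boundaries (weights fading
from 1 at the ILM to 0 at the outer bands; default depth 60 px, width
40 px), optional sinusoidal curvature standing in for peripapillary
geometry, vertical vessel shadows (multiplicative darkening below the ILM),
dark elliptical fluid blobs with exact masks, and multiplicative Gaussian
speckle $I\cdot(1+\mathcal N(0,\sigma))$, clipped — all reproducible from
one integer seed with a locally scoped RNG.

They do **not** emulate: true multiplicative speckle statistics (Rayleigh /
gamma), the axial point-spread function, depth-dependent attenuation and
shadowing under fluid, Henle-fiber obliquity under the OPL, motion
artifacts, or real pathology morphology. Passing the recovery tests
therefore demonstrates that the machinery is correct and self-consistent
under controlled contrast and noise — not that clinical accuracy equals the
sub-pixel figures seen on phantoms. On real scans the limiting factors are
precisely the ones the phantom idealizes away.

Simulated clicks place anchors at grid-line columns (endpoints forced to
the image edges) on the true boundary with 1 px Gaussian jitter, and rim
clicks at equal arc length around a fluid component — click counts of 5
(ILM), 6 (IPL–INL) and 9 (OPL–ONL) mirror the relative effort those
boundaries demand in interactive use.

## Problem sizes and tolerances used by the automated checks

The test-suite and the acceptance script run, per invocation: 50 random
grids up to 12 × 12 against a Bellman–Ford oracle (exact cost equality);
20 random flatten/unflatten roundtrips (bit-exact); 20 vessel layouts with
2–4 shadows at twice the detection threshold (100% recall and precision,
centres within ±1 column); 20 full phantoms at σ = 0.05 with jittered
clicks (mean unsigned error ≤ 2 px per boundary — the tolerance mirrors the
~2 px disagreement typical between expert graders, and the measured values
are an order of magnitude below it); 10 ellipse phantoms with 5 rim clicks
(Dice ≥ 0.85; measured ~0.93); and one full CLI pipeline executed twice
(byte-identical outputs). These sizes complete in well under a minute on a
single CPU while exercising every code path; they are statements about this
package's correctness, not reproductions of any clinical study.

## Known limitations

* Cost images are built per boundary from a global gradient normalization;
  extremely low-contrast interfaces can require per-boundary `gamma` or
  ROI tuning through the JSON config.
* The peripapillary reference estimator assumes a single dominant bright
  outer complex; severe pathology that fragments the photoreceptor–RPE
  band would need externally supplied reference anchors.
* Closed-contour tracing assumes the rim is at least partially visible;
  for fluid with completely invisible walls the tracer degrades to the
  anchor polygon (which is also the sensible manual fallback).
* The CLI is batch-only by design; interactive clicking, freehand drawing
  and on-screen rendering are out of scope.
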