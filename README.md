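# octlivewire

Semi-automatic, graph-based segmentation of retinal layer boundaries and
fluid pockets in optical coherence tomography (OCT) B-scans, with the
evaluation metrics used to validate such segmentations, a synthetic phantom
generator with exact ground truth, and a batch command-line interface.

## Who this is for

Manual delineation of retinal interfaces (ILM, IPL–INL, OPL–ONL, ...) in
macular and peripapillary OCT is slow and error-prone, and fully automatic
methods degrade on low-quality or pathological scans (e.g. diabetic macular
edema). The live-wire compromise lets an operator supply a handful of
clicks per boundary while the computer fills in the curve by following
image evidence. This package implements that pipeline in batch form — user
clicks are anchor points supplied from CSV files or from a simulated-click
generator — so the method itself can be developed, stress-tested and
evaluated reproducibly without a GUI.

## The method

A B-scan is viewed as an 8-connected pixel graph. The edge between
neighbouring pixels *a* and *b* costs

    w(a, b) = (c(a) + c(b)) / 2 * (sqrt(2) if diagonal else 1)

where *c* is a strictly positive per-pixel cost. A boundary traced through
anchor clicks is the concatenation of Dijkstra shortest-path-first (SPF)
minimum-cost paths between consecutive anchors — the classic live-wire
formulation.

Raw OCT boundaries are too faint for this to work directly, so each
interface gets its own preprocessed *background* image: Gaussian denoising,
a polarity-rectified vertical gradient (each retinal interface is either a
dark-to-light or a light-to-dark transition in depth), morphological
closing/opening along the boundary direction, gamma contrast, and a
region-of-interest mask derived from already-traced neighbouring
boundaries. The cost is `(1 - edge) + eps`, making the target interface the
cheapest ridge in its search region.

Additional components:

* **Grid fallback** — interpolates a full-width boundary through one click
  per vertical grid line (shape-preserving monotone cubic, linear
  extrapolation to the image edges).
* **Peripapillary mode** — flattens the scan with a per-column circular
  shift vector computed from a reference boundary
  (`shift = max(z_ref) - z_ref`), detects vessel shadows as prominent local
  minima of the column-mean profile below IPL–INL, repairs them by
  adjacent-column substitution, traces 8 boundaries (no GCL–IPL) and maps
  them back to original coordinates.
* **Fluid delineation** — closed live-wire contours over a Canny +
  morphological-closing edge background, rasterized to masks with
  8-connected components and small-object filtering.
* **Metrics** — unsigned boundary error `sum(|x_i - y_i|)/w` (px),
  irregularity index `L_r / L_b` (chord-to-arc ratio), Dice overlap
  `2|X∩Y|/(|X|+|Y|)`, Bland–Altman bias / 95% limits of agreement,
  gold-standard averaging across graders, repeatability reports.
* **Phantoms** — layered B-scans (496 x 512 by default) with smooth
  curvilinear boundaries, foveal pit, optional sinusoidal curvature, vessel
  shadows, elliptical fluid blobs, multiplicative speckle, and exact ground
  truth plus simulated clicks.

## Worked example

```r
library(octlivewire)

# a seeded phantom with ground truth and simulated clicks
ph <- generate_bscan(phantom_spec(seed = 3))
anchors <- list(
  ILM     = simulate_clicks(ph$boundaries$ILM,     5, jitter_sigma = 1,
                            seed = 4, height = 496),
  IPL_INL = simulate_clicks(ph$boundaries$IPL_INL, 6, jitter_sigma = 1,
                            seed = 7, height = 496),
  OPL_ONL = simulate_clicks(ph$boundaries$OPL_ONL, 9, jitter_sigma = 1,
                            seed = 9, height = 496))

traced <- segment_macular(ph$image, anchors)
for (lab in names(traced))
  cat(lab, "mean unsigned error:",
      round(unsigned_error(traced[[lab]], ph$boundaries[[lab]]), 3), "px\n")
```

```
ILM mean unsigned error: 0.298 px
IPL_INL mean unsigned error: 0.207 px
OPL_ONL mean unsigned error: 0.131 px
```

Each line is the mean per-column absolute depth difference between the
live-wire trace (from 5–9 jittered clicks) and the generator's exact
boundary — here a fraction of a pixel, comfortably inside the ~2 px
disagreement typical between expert graders.

The same pipeline is scriptable from a shell via `inst/cli/oct-livewire`
(`convert`, `segment-layers`, `grid`, `correct`, `fluid`, `peripapillary`,
`metrics`, `phantom` subcommands).

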