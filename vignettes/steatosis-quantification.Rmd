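---
title: "Quantifying hepatic steatosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic steatosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoquant)
```

## The problem

Hepatic steatosis — fat accumulation in the liver — is graded in rodent
fatty-liver models partly by how many lipid droplets a section contains
and how large they are: many small (microvesicular) versus few large
(macrovesicular) droplets carry different pathological meaning. In H&E
histology the droplets are unstained, so they appear as bright,
near-circular vacuoles on pink tissue. `steatoquant` turns a scanned
section into a per-droplet table (centre, radius, diameter in µm, area
in µm²), a size histogram, and a between-group test for a size-shift.

## Detection model and assumptions

The detector assumes droplets are approximately circular, brighter than
the surrounding tissue, and mostly non-coalescent. It proceeds in four
deterministic stages:

1. **Luminance.** RGB is collapsed with fixed Rec.601 weights
   (`0.299, 0.587, 0.114`). Vacuoles are near-white, so any monotone
   luminance would work; a fixed formula keeps results bit-stable.
2. **Segmentation.** Otsu's threshold on the luminance histogram (a
   fixed threshold is available for unusual staining). Components
   smaller than `min_component_px` (4-connectivity) are dropped as
   speckle. A zero-variance image is defined to contain no vacuoles,
   since Otsu is undefined there. Because Otsu depends only on the
   histogram, a uniform brightness offset (no clipping) does not change
   the mask — detections are invariant to global illumination shifts.
3. **Circular Hough transform.** Mask boundary pixels (mask pixels with
   a background 4-neighbour; pixels beyond the image edge count as
   background) vote for every centre at each search radius, along the
   *rasterized* circle perimeter. Scores are votes divided by the ideal
   perimeter pixel count for that radius, so a score of 1 means the
   entire rim is present and large radii gain no advantage. Peaks are
   accumulator cells at or above `vote_threshold` that are maximal in
   their 3 × 3 × 3 `(cy, cx, r)` neighbourhood; plateau ties are all
   kept and resolved by suppression.
4. **Suppression and filtering.** Greedy non-maximum suppression in
   descending score order removes candidates whose centre is within
   `nms_center_factor · (r_kept + r_cand)` of a kept circle; ties break
   towards the larger radius (when the evidence is ambiguous, the
   macrovesicular reading is preferred), then lexicographic centre, so
   output order is fully reproducible. Survivors must have ≥
   `fill_min` of their in-image disk mask-positive (rejects rim-only
   structures such as sinusoids and vessel cross-sections) and ≥
   `border_inside_min` of their disk inside the image (the usual
   discard-edge-objects rule).

One disk definition — pixels with `(y−cy)² + (x−cx)² ≤ r²` — is shared
by the renderer, the Hough perimeter kernels, and the fill filter, so
the geometry tests in the suite are exact rather than approximate.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `r_min`, `r_max` | 3, 30 | px | radius search range; covers ~3–60 µm diameters at 0.5–1 µm/px |
| `r_step` | 1 | px | integer radius grid (see below) |
| `vote_threshold` | 0.5 | fraction | ≥ half the rim must be supported |
| `nms_center_factor` | 0.75 | fraction | suppression radius as a fraction of the radius sum |
| `fill_min` | 0.6 | fraction | minimum mask fill of the disk |
| `border_inside_min` | 0.9 | fraction | minimum disk fraction inside the image |
| `segmentation` | `"otsu"` | – | threshold rule; a number fixes it |
| `min_component_px` | 9 | px | speckle floor for mask components |
| `um_per_px` | 1 | µm/px | physical calibration, always user-supplied |

Centres and radii are kept at integer resolution. Sub-pixel refinement
was considered and rejected: it would break the exact equivalence
between the fast accumulator and the exhaustive brute-force reference
used in testing, and a ≤ 0.5 px gain is irrelevant against µm-scale
biology.

The calibration is deliberately an input, never inferred: scanned
sections state their scale only via a scale bar, and reading scale bars
from pixels (OCR) is out of scope. All coordinates are 0-based
`(row, col)` with row 0 at top, in every report and ground-truth file.

## Measurement, binning, comparison

With calibration `s` µm/px, diameter `= 2rs` µm and area `= π(rs)²`
µm². Histogram bins are half-open `[lo, hi)` with explicit underflow
and overflow counters, so no droplet is double-counted or silently
dropped: `sum(counts) + underflow + overflow = total` always holds.

Two groups are compared with the Cochran–Armitage chi-square test for
trend on the pooled 2 × K bin-count table (equally spaced integer
scores, population-variance form, df = 1, upper-tail p). Pooling treats
the droplet as the counting unit — group histograms are summed across
images — matching how per-droplet size distributions are usually
plotted; a per-animal stratified variant is deliberately not offered.
Underflow/overflow lie outside the user's chosen size range and are
excluded from the test. The statistic is invariant to affine changes of
the scores and to swapping the group labels.

Two numerical caveats, both verified in the test suite:

* The chi-square p agrees with a margin-conditioned permutation p
  (Monte-Carlo, same statistic) to within 0.02 on small tables with a
  clear trend. For mid-range p (roughly 0.05–0.15) at N ≤ 30 the
  permutation null is so discrete that single tie masses exceed 0.02 —
  there the asymptotic p is systematically smaller than the exact one,
  a property of the test itself, not of this implementation. With
  droplet counts in the hundreds (pooled across images) the
  approximation is excellent: under a shared-multinomial null at
  N = 200 the measured type-I rate at α = 0.05 lies within [0.03, 0.07].
* Degenerate inputs fail loudly: an empty group row and score-constant
  occupied bins are errors, not NaNs.

`summary_ttest()` re-tests published "mean ± SEM (n)" pairs with a
Welch t (variances estimated independently from the SEMs, two-tailed);
`positive_area_fraction()` is a plain thresholded pixel fraction with a
multi-field mean variant, each field weighted equally.

## The synthetic-histology generator

`synthetic_spec()` defines the package's standard study conditions: a
256 × 256 px field, 15 non-overlapping droplets, integer radii uniform
on 5–25 px, eosin-pink background (230, 180, 190), near-white droplets
(250, 250, 250), and i.i.d. Gaussian channel noise with σ = 5 clipped
to [0, 255]. These sizes emulate the micro-to-macrovesicular range at
typical scan resolution, at a density where droplets remain mostly
resolvable; σ = 5 approximates sensor/compression noise without
texture. Placement is rejection sampling with a 2 px margin between
circles and to the borders (margin chosen once: 4-neighbour boundaries
of adjacent disks must not merge during segmentation, which one free
pixel guarantees and two make robust to noise). An `allow_overlap` mode
exists to probe the detector's failure mode on fused droplets, but
carries no accuracy claim. A lognormal radius option (truncated,
rounded) provides right-skewed size distributions.

What the generator does **not** emulate: nuclei and sinusoid texture,
stain variation, uneven illumination, out-of-focus blur, and partially
coalesced droplets with concave outlines. Passing the synthetic
benchmark therefore demonstrates that the geometry, voting, calibration
and statistics are correct — not that segmentation is robust to every
real-slide artifact; on real material the segmentation threshold and
fill parameters may need adjustment.

Determinism is strict throughout: the generator is a pure function of
`(spec, seed)` (the caller's RNG state is saved and restored), detection
is deterministic given image and parameters, and the CLI writes
byte-identical files for identical argv and inputs (atomic temp-file +
rename writes, fixed 6-decimal serialization).

## Validation design

* **Brute-force Hough oracle.** On small fields the fast C++ accumulator
  is required to equal, peak set for peak set, an independent R
  implementation that builds the full accumulator by shift-and-add and
  re-derives peak selection and suppression from the rules.
* **Ground-truth benchmark.** 50 fields at the standard conditions
  (seeds 1–50); pooled precision, recall, and centre/radius MAE under
  3 px matching, plus a two-sample KS test of detected vs true radii.
  Matching is greedy one-to-one in ascending centre distance; precision
  and recall are defined as 1 when their denominator is empty.
* **Trend-test calibration.** Closed form checked against
  `stats::prop.trend.test` and a 10⁵-draw permutation oracle on a
  hand-evaluated table; type-I rate at N = 200 over 2000 replicates;
  power ≥ 0.8 demanded against a one-bin (10 µm diameter, i.e. 5 px
  radius) upward shift of group B's radius distribution with 6
  images per group — the shift magnitude is fixed at exactly one bin
  width, the stochasticity being the sampling itself.

Problem sizes (50 benchmark fields, 20 oracle instances, 2000 null
replicates, 200 power seeds) are the package's standard validation
scale; they keep the full suite under a minute of compute while holding
Monte-Carlo error on the reported rates to a few parts in a thousand.

## Known limitations

* Circles only: elliptical or coalesced droplets are under-segmented;
  watershed splitting and ellipse fits are out of scope.
* Whole-slide formats (SVS/NDPI) and stain deconvolution are not
  handled; export fields as PNG/TIFF first. JPEG is refused.
* The segmentation is a global threshold; strongly vignetted or
  unevenly illuminated fields should be flat-fielded upstream.
* The trend test pools droplets across animals; inference is at the
  droplet, not animal, level, as is usual for these distribution plots.
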