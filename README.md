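# steatoquant

Quantifying hepatic steatosis from liver histology. In H&E-stained liver
sections, lipid droplets are unstained and appear as bright, near-circular
vacuoles against pink tissue; their number and size distribution (micro-
vs macrovesicular steatosis) are a primary readout in fatty-liver-disease
models. `steatoquant` detects these vacuoles as circles, measures each one
in physical units, and compares droplet-size distributions between animal
groups. It is aimed at researchers quantifying steatosis or stained-area
fractions from scanned sections, and ships a synthetic-histology
generator so every stage can be validated against known ground truth.

## Method

**Detection** is a circular Hough transform on the segmented vacuole
mask. The luminance image (Rec.601, `L = 0.299R + 0.587G + 0.114B`) is
thresholded by Otsu's method; mask boundary pixels *p* then vote for
every candidate centre `c = p − o`, with `o` running over the rasterized
perimeter offsets of each search radius `r`. Accumulator cells are
normalized by the ideal perimeter pixel count of their radius, so the
score is the supported fraction of the rim (radius-unbiased, 1 for a
complete circle). Local accumulator maxima with score ≥ 0.5 are reduced
by greedy non-maximum suppression (a candidate is suppressed within
`0.75 (r_kept + r_cand)` of a kept centre), then filtered: at least 60 %
of the disk must be mask-positive and at least 90 % of it must lie
inside the image.

**Measurement**: with calibration `s` µm/px, a circle of radius `r` px
has diameter `2rs` µm and area `π(rs)²` µm². Droplets are tallied into
half-open size bins `[lo, hi)`.

**Group comparison** uses the Cochran–Armitage chi-square test for
trend on the pooled 2 × K table of bin counts, with scores
`s_k = 0, …, K−1`:

```
X² = N (N Σ s_k n_1k − R₁ Σ s_k C_k)² / [ R₁R₂ (N Σ s_k² C_k − (Σ s_k C_k)²) ],  df = 1
```

**Stained-area fraction** (`positive_area_fraction()`) quantifies e.g.
Picrosirius-red collagen staining as positive pixels / total pixels,
averaged over fields per section.

## Worked example

```r
library(steatoquant)

spec <- synthetic_spec(n_droplets = 10, seed = 3)   # 256x256 H&E-like field
sim  <- simulate_histology(spec)                    # image + ground truth
det  <- detect_droplets(sim$image, um_per_px = 0.5)
det
#> Droplet detection: image (256 x 256 px, 0.5 um/px)
#>   10 droplets kept (of 10 Hough candidates; 7246 mask px)
#>   radius range 9..23 px, median score 1.00

rec <- measure_droplets(det)
head(rec[, c("droplet_id", "cy", "cx", "r_px", "diameter_um", "area_um2")], 3)
#>   droplet_id  cy  cx r_px diameter_um area_um2
#> 1          1  94  64   23          23 415.4756
#> 2          2 167 176   22          22 380.1327
#> 3          3  22 182   16          16 201.0619

bin_histogram(rec, c(0, 5, 10, 15, 20, 25))
#> Droplet size histogram on diameter_um (10 droplets)
#>   [0, 5)  [5, 10) [10, 15) [15, 20) [20, 25)
#>        0        1        5        2        2
```

All ten synthetic droplets are recovered with a full supported rim
(score 1), and the pixel radii convert to 9–23 µm diameters at the
0.5 µm/px calibration. Comparing two groups of binned histograms:

```r
chi_square_trend(rbind(c(10, 5, 1), c(4, 6, 8)))
#>  Chi-square test for trend (Cochran-Armitage)
#> X-squared = 7.9654, df = 1, p-value = 0.004768
```

a significant upward size shift in the second group.

The same pipeline is available from the shell via the installed
launcher (`system.file("cli", "steatoquant", package = "steatoquant")`):
subcommands `simulate`, `detect`, `report`, `compare`, `areafrac`; see
`run_cli(c("simulate", "--help"))`.

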