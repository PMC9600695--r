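---
title: "Quantifying colony wrinkling, growth and sporulation with colonyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony wrinkling, growth and sporulation with colonyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyscreen)
```

# Scope

`colonyscreen` implements the quantitative machinery of a high-throughput
phenotypic screen of *Bacillus subtilis* NCIB 3610 colony arrays: an
image-analysis pipeline that scores biofilm colony wrinkling on agar plates,
colony size and reporter-fluorescence measurement on an inferred colony grid,
growth/no-growth calls and lag-time extraction from plate-reader OD600
series, sporulation quantification from outgrowth lags and serial-dilution
CFU spots, a gene-by-gene proteome comparison, and a synthetic-data generator
that produces all of these inputs with known ground truth. Everything is
deterministic given its inputs; the generators are pure functions of a spec
and a seed.

# The wrinkling metric

Mature *B. subtilis* biofilm colonies buckle into macroscopic ridges.
Wrinkling has usually been scored by eye as a binary phenotype; the pipeline
here turns it into a number per colony.

The key observation is one of spatial scale: wrinkle ridges are narrow
(a few pixels at typical magnification), while everything else in the image —
the colony body, the agar, uneven illumination — varies smoothly over tens of
pixels. A grayscale morphological **opening** with a disc structuring element
of radius `disk_radius_px` (default 15 px) erases any bright structure
narrower than the disc while following wider structures exactly, so
`image - opening(image)` (the top-hat residual) isolates the ridges and
removes illumination gradients in the same stroke. The residual is then
contrast-stretched (1st–99th percentile window mapped to [0, 1], clipped),
binarized at `binarize_level` (default 0.5 of the stretched range; an Otsu
threshold is available as an option), and connected components smaller than
`min_component_px` (default 50 px, 8-connectivity) are removed as
segmentation debris.

Because opening and subtraction commute with a global intensity scaling and
the percentile stretch removes the scale, the mask is exactly invariant to
multiplying all intensities by a positive constant — exposure differences
between plates do not move the metric.

Colonies sit on a known lattice: the centre of one corner colony plus the
grid spacing (9 mm between adjacent colony centres on the screen's plates)
determines every other centre, so no per-colony detection is needed
(`infer_grid()`). For each colony the **radial wrinkling intensity** $W(r)$
counts mask pixels within distance $r$ of the centre (squared-integer
comparisons; the counts are exact and non-decreasing in $r$), and the
**wrinkling density** is

$$\mathrm{density} = \frac{W(R)}{A(R)} \in [0, 1],$$

where $R$ is the measured colony radius and $A(R)$ the number of lattice
pixels in the radius-$R$ circle. Densities are divided by the mean density
of the parent-strain control colonies spotted on the same plate, and a
colony is called a **low wrinkler** when its normalized density falls
strictly below 0.2. High wrinklers have no equally principled published
cutoff (they were curated by eye in the original screen), so `high_cutoff`
defaults to `Inf` and must be set deliberately.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `disk_radius_px` | 15 | px | must exceed the ridge half-width and stay below the colony radius; "size 15" is read as a radius, the common structuring-element convention, and is configurable because the convention is ambiguous |
| `min_component_px` | 50 | px | removes binarization speckle; anything smaller than ~1/3 of a ridge segment is unlikely to be a wrinkle |
| `binarize_level` | 0.5 | — | midpoint of the stretched residual range, the standard default for this binarization |
| `stretch_percentiles` | (1, 99) | % | the usual saturation window; makes the stretch robust to a few extreme pixels |
| `spacing_mm` | 9 | mm | centre-to-centre colony pitch of the arrayed plates |
| `low_cutoff` | 0.2 | — | the screen's published low-wrinkler cutoff relative to internal controls; ties are not low (strict `<`) |

# Colony size and fluorescence

Colony diameter mirrors the manual measurement the screen performed in an
image viewer: the intensity profile along the 45° diagonal through the
colony centre, with the diameter taken between the two outermost crossings
of a threshold set at the midpoint of the profile's 5th and 95th
percentiles. The relative threshold makes the measurement invariant to a
constant intensity offset. On gridded plates the profile is truncated at
`0.7 * pitch` so the diagonal neighbour cannot contribute a crossing.

Reporter fluorescence is measured over a fixed circle (the screen used "a
circle the size of the largest colony"; the radius is a parameter because
the original choice per plate versus per experiment is not recorded). Two
readouts: `(raw - blank) / (reference - blank)`, with blank and reference
taken from designated control colonies on the same plate (invariant under
affine intensity rescaling); and blank-corrected total intensity per mm² for
the matrix-promoter reporter assay.

# Growth calls and lag times

Plate-reader curves are blank-corrected by subtracting the *minimum* reading
of a blank well (clipping at zero — the minimum rule can overshoot) or
passed through when plates were pre-blanked. A strain **fails to grow** when
its OD600 is strictly below 0.075 at the call time (5 h for LB, 8 h for the
biofilm medium MSgg); the OD at the call time is linearly interpolated
between flanking samples, and a value exactly at the threshold counts as
growth, preserving the strictness of the "< 0.075" criterion. **Lag time**
is the first crossing of OD 0.2, again linearly interpolated; curves
starting above the threshold have lag 0 and curves that never reach it are
censored, not zero. Interpolation is linear in OD rather than log-OD: it is
the simplest defensible reading of a threshold rule applied to sampled
curves, and at 15-min sampling the two differ by far less than a sampling
interval.

# Sporulation quantification

After growing a culture for 24 h, vegetative cells are heat-killed (80 °C,
30 min) and the survivors — spores — are quantified two ways.

**CFU spotting.** Serial 10-fold dilutions are spotted (10 µL per spot) and
colonies counted. The estimator takes the most-concentrated dilution whose
count falls in the countable window of 3–30 per spot and computes
`count / spot_volume / dilution`. The window is this package's choice (the
original work reports CFU without stating one): below 3 the relative Poisson
error exceeds ~60 %, above ~30 colonies merge in a 10-µL spot. Among
countable spots the most concentrated is used because the largest count has
the smallest relative Poisson error. An all-zero series is below the
detection limit; an all-overgrown series is an error, not a guess. The
**sporulation efficiency** is the ratio of post- to pre-heat-kill CFU/mL —
~1 for a sporulation medium (DSM), around 10⁻⁴ for LB — reported as a
fraction, flagged but not clipped when noise pushes it above 1.

**Outgrowth lag.** Diluted post-heat-kill cultures regrow after a lag that
lengthens by $\log_2(10) \cdot t_d$ per missing decade of spores — about
1.107 h per 10-fold dilution at the ~20 min effective doubling time
(`expected_lag_shift()`). Ordinary least squares of lag on
$\log_{10}(\text{spores})$ (`fit_lag_calibration()`, unweighted — the
original fit's weighting is unrecorded) recovers this slope and inverts to
predict spore counts from lags (`predict_spore_count()`). One spore in the
1 µL transfer volume sets the detection limit of 10³ CFU/mL of the original
culture (`detection_limit()`).

# The synthetic-data generator

The generators exist so every pipeline stage can be tested against known
ground truth; their defaults are fixed once to match the screen's
conditions and are not tuned per test.

`synth_plate_image()` draws an 8 × 12 colony array at 9 mm spacing,
0.1 mm/px, colony radius 2.5 mm, on agar background 0.25 with colony
plateau 0.55. Each colony is a **flat-topped dome** (plateau to 0.7 R, then
a cosine shoulder): a wide smooth shape that a radius-15 disc opening
reconstructs almost exactly, so an unwrinkled colony leaves essentially no
top-hat residual. Ridges are random quadratic Bézier arcs of width 3 px —
narrower than the opening disc, so they survive background subtraction —
stamped until the target fraction of colony pixels carries ridge (the truth
records the *achieved* fraction). A planar illumination gradient
(peak-to-peak 0.05) checks the pipeline's illumination robustness, and
Gaussian sensor noise (sd 0.005) is added last. The image also carries a
thin bright **plate-wall frame**, as real plate photographs do: a genuine
image feature that additionally anchors the global contrast stretch — on a
plate with no wrinkles at all, the stretch normalizes to the frame rather
than amplifying sensor noise to full range, just as the plate wall and
residual texture do in real photographs — and gives the automatic rotation
estimator a straight edge to find.

`synth_growth_curve()` produces
$\mathrm{OD}(t) = \min\!\big(K,\; c\,N_0\, 2^{\max(0,\,t - t_{\mathrm{lag}})/t_d}\big) + \varepsilon$
with $t_d = 20$ min, a 1 h germination offset, carrying capacity 1.4,
$c = 6.25\times10^{-9}$ OD per cell in a 200 µL well (OD 1 ≈ 8 × 10⁸
cells/mL), 15-min sampling over 24 h and additive Gaussian OD noise
(sd 0.003, no heteroscedasticity — nothing in the assay constrains the
noise model and the tests do not depend on it). The closed-form lag to
OD 0.2 is returned as truth. `synth_outgrowth_series()` chains 10-fold
dilutions, drawing the realized inoculum from a Poisson distribution (so
sub-single-spore dilutions go flat with probability $e^{-\lambda}$) or
using the expectation exactly for closed-form checks.
`synth_spot_counts()` draws counts from
$\mathrm{Poisson}(\mathrm{CFU/mL} \times \mathrm{volume} \times \mathrm{dilution})$.

## What the synthetic data does not emulate

Passing on synthetic plates shows the algorithms compute what they claim on
images satisfying their assumptions; it does not certify performance on
real photographs. In particular the generator produces radially symmetric
colonies with uniform coloring — the original screen documented a colony
misclassified because of non-wild-type coloring, a failure mode the
pipeline does not correct — and no lens distortion, specular highlights,
condensation, or agar texture. No flat-field calibration or multi-plate
registration is attempted. The sporulation screen's own caveat carries
over: outgrowth delay cannot distinguish fewer spores from slower
germination.

# Numerical choices and conventions

* Pixel coordinates are 1-based `(row, col)` pairs, matching R's matrix
  indexing; circle membership is Euclidean distance from the pixel centre
  `<= r`, compared on squared integers wherever radii are integral, so
  counts are exact and grid arithmetic round-trips to machine precision.
* The grayscale conversion uses fixed luminance weights
  0.2126/0.7152/0.0722.
* Rotation is bilinear about the image centre, padding with the median
  border intensity and clipping back to [0, 1]; rotation by 0 is the
  identity on pixels. Automatic skew estimation thresholds at the Otsu
  level, takes the largest 8-connected component, and uses the orientation
  of its minimum-area bounding rectangle folded into (−45°, 45°]; a
  featureless image falls back to 0 with a warning.
* A featureless top-hat residual (constant image) yields an empty mask
  rather than a divide-by-zero stretch.
* Component labeling is 8-connected by default (the usual convention for
  this removal step) and is implemented in the package; tests verify it
  against an independent flood-fill.
* Ties: exactly 0.2 normalized density is *not* low; OD exactly 0.075 at
  the call time *is* growth; the first threshold crossing defines lag even
  if the curve later dips.
* Efficiency is a fraction; percent formatting belongs to presentation
  layers.

# Problem sizes

The validation suite runs entirely on synthetic data at sizes chosen to
exercise the algorithms well within a laptop's patience: oracle-equivalence
checks compare the mask pipeline against brute-force morphology on 100
random images up to 64 × 64; plate-level properties use a full 96-colony
plate (750 × 1110 px); Monte-Carlo checks of the CFU estimator use 500–1000
seeded Poisson replicates; calibration recovery uses 50 noisy points
spanning five decades of spore counts.

# A worked example

```{r example}
# a 96-colony plate with five generated wrinkle levels
fr <- rep(c(0, 0.05, 0.1, 0.2, 0.4), length.out = 96)
syn <- synth_plate_image(synth_plate_spec(wrinkle_fraction = fr, seed = 303))
mask <- preprocess_to_mask(syn$image)
R <- floor(syn$truth$colony_radius_px)
dens <- vapply(seq_len(96), function(k)
  wrinkling_density(radial_profile(mask, syn$grid$centers_px[k, ], R), R),
  numeric(1))
round(tapply(dens, fr, mean), 3)  # mean measured density per generated level
```

```{r example2}
# outgrowth lags of a noiseless 10-fold dilution series
ser <- synth_outgrowth_series(1e5, 5, synth_curve_spec(noise_sd = 0, seed = 17),
                              sample_poisson = FALSE)
lags <- vapply(ser$curves, function(cv) lag_time(cv)$lag_h, numeric(1))
round(diff(lags), 3)           # ~1.107 h per decade
expected_lag_shift(10, 20)     # the closed form
```

# Known limitations

Colony centres come from the grid prior; there is no automatic colony
detection, so a mis-clicked corner shifts every measurement. The wrinkle
metric conflates any narrow bright structure with wrinkles (dust,
reflections). Diameter measurement assumes colonies brighter than
background along the diagonal. The lag calibration assumes a common
doubling time across strains; strains with growth-rate defects violate it.
The proteome comparison pairs records by gene-name token and reports
unequal-length pairs without aligning them.
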