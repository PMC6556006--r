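---
title: "Quantitative neuropathology with npq: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative neuropathology with npq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npq)
library(dplyr)
```

`npq` implements a quantitative neuropathology workflow for brightfield
immunohistochemistry (IHC) and community autopsy cohorts: stain
deconvolution and burden metrics for pTau, inclusion counting for pTDP-43,
a synaptic-integrity ratio for the hippocampal perforant pathway, stringent
selection of resistant and resilient cases with matched dementia controls,
ordinal and composite pathology scoring, exact matched-pair statistics, and
Mendelian segregation tests for transgene crosses. This vignette explains
the underlying models, the tunable parameters, and the choices made where
the methods left genuine freedom.

## Stain physics: Beer–Lambert and color deconvolution

Brightfield absorbance is linear in stain amount on the optical-density
(OD) scale, `OD = -log10(I / I0)`. We use the 8-bit convention `I0 = 255`
throughout, with a 1-intensity-unit floor so that saturated pixels clamp at
`OD = log10(255) ≈ 2.407` rather than diverging. A slide stained with a
hematoxylin counterstain and the brown DAB chromogen mixes two absorbance
spectra per pixel; with unit RGB OD vectors for each stain (plus a residual
component that absorbs off-axis signal) the per-pixel mixture is a 3×3
linear system, solved exactly by `deconvolve()`. The default vectors —
hematoxylin (0.67, 0.66, 0.339), DAB (0.311, 0.522, 0.794), residual
(0.02, 0.999, 0.02) — are values measured on human brain sections in
single-stain regions; stain-vector estimation from data is deliberately
out of scope, as the workflow assumes calibrated vectors are supplied.
Negative unmixed concentrations (off-model pixels, e.g. pigment artifacts)
are clipped to zero, the standard practice.

```{r deconv}
m <- stain_model()
img <- render_ihc_image(
  width_px = 120, height_px = 120, noise_sd = 0,
  objects = tibble::tibble(x = 60, y = 60, shape = "disk",
                           area_um2 = 80, dab_od = 1),
  seed = 1)
maps <- deconvolve(rgb_to_od(img$image), m)
range(maps$dab)   # recovers the planted OD exactly at zero noise
```

Thresholds in the slide-analysis tools are quoted on the 0–255 intensity
scale of the *deconvolved* DAB channel, so `stain_to_intensity()` maps a
single-stain OD map back through `I = 255·10^-OD`. Whether a commercial
analyzer's "intensity" is this pseudo-intensity or a raw channel intensity
is not documented anywhere we could verify; both segmentation (220) and
positivity (200) thresholds are plain parameters, so either reading can be
configured.

### The positive-area burden metric

`area_analysis()` counts ROI pixels whose DAB pseudo-intensity is *below*
the upper positive threshold (default 200): "exceeding" a threshold is
read as exceeding in stain darkness. Only this direction makes a threshold
of 200 select stained (dark) pixels, and makes the calibration narrative —
start at the highest value and reduce until background disappears —
coherent. The reported burden is `OD × %Positive`: the mean OD over
positive pixels times the percent of the ROI positive, a weighted metric
that grows with both extent and darkness of staining. It is exactly zero
when nothing is positive, and is invariant to where in the ROI the
staining sits.

Regional tau burdens also feed the limbic-predominant subtype rule
(`tau_subtype_ratio()`): a hippocampus/MFG burden ratio strictly above 1.5
labels a case limbic-predominant.

### Regions of interest

ROIs are simple polygons in 0-based pixel coordinates, mimicking freeform
pen annotations. A pixel belongs to an ROI iff its *center* lies inside
the polygon under the even-odd rule — unambiguous and testable. ROI area
is the member-pixel count times the pixel area, which makes object
densities exactly additive when an ROI is tiled. Pigment artifacts
(lipofuscin, hemosiderin) are not modeled; callers can subtract them by
supplying tighter polygons.

## Inclusion detection and counting

`segment_candidates()` finds pTDP-43-positive objects in three steps:

1. **Smoothing.** Gaussian blur with σ equal to the smoothing radius
   (default 2 μm, converted to pixels via the image's pixel size).
2. **Thresholding.** Pixels with smoothed DAB intensity below the
   segmentation threshold (default 220) form the candidate foreground.
3. **Declustering.** Touching clusters are split by a watershed on stain
   darkness of the smoothed map; two adjacent basins are merged when the
   saddle between them is shallower than the merging threshold (default
   2.5 intensity units). The commercial declustering algorithm this
   emulates is proprietary; watershed-with-saddle-merging reproduces its
   qualitative split/merge behavior with a single interpretable knob, and
   we document it prominently as our own stand-in interpretation.

Each object's features are then measured on the *unsmoothed* map: the blur
decides connectivity, but measuring sizes on the blurred map would inflate
them. Area is pixel count times pixel area; the perimeter uses the
Cauchy–Crofton four-direction estimate, which (unlike the naive pixel-edge
count, biased ~27% high for disks) converges to the true perimeter for
large smooth shapes, so roundness `4πA/P²` of a disk approaches 1.
Elongation is the minor/major axis ratio of the second-moment ellipse,
with a 1/12-pixel variance regularization so a one-pixel-wide bar is a
thin bar rather than a degenerate line. `filter_objects()` applies the
calibrated restrictions — area 20–225 μm², roundness ≥ 0.25, elongation ≥
0.1, mean DAB intensity ≤ 200 — and `count_density()` reports objects per
mm² of annotated area.

### Threshold calibration

The positivity threshold (200) was originally calibrated from five
positive and five negative training slides by extracting histograms of
object counts per intensity unit and choosing the point capturing the 99th
percentile of positive-slide objects while staying at or below the 60th
percentile of negative-slide objects. `calibrate_positive_threshold()`
implements this on *pooled* cumulative fractions; whether the original
rule pooled slides or operated per slide is not specified, and pooling is
the simpler estimator of the cohort-level operating point. If no threshold
satisfies both constraints (e.g. overlapping distributions), the threshold
maximizing the positive-minus-negative capture gap is returned with an
`unconstrained` flag rather than silently pretending separation.

## Perforant-pathway synaptic integrity (RIR)

Entorhinal afferents terminate in the outer molecular layer of the dentate
gyrus, so synaptophysin staining there, relative to the inner molecular
layer, indexes perforant-pathway synapse loss. The relative
immunointensity ratio is `(outer − blank)/(inner − blank)` on mean 8-bit
intensities, with the blank region normalizing each slide. Intensities are
measured on the raw image (luminance), matching manual densitometry
practice; a deconvolved-channel variant is possible by passing a stain map
instead. The ratio is scale invariant in distance-from-blank, equals 1 for
symmetric staining, and falls toward 0 with preferential outer-layer loss.
At low OD the intensity scale is near-linear in stain amount, so a planted
outer/inner stain-density ratio is recovered to within a few percent;
Beer–Lambert curvature makes the mapping progressively sublinear at high
OD, which is why the measurement regions should avoid saturated staining.

## Cohort selection and matching

Selection uses only criteria available for every autopsy:

* **Resistant**: non-demented, last CASI within 2 years of death, Braak ≤
  III, CERAD none, age at death ≥ 85.
* **Resilient**: non-demented, last CASI within 2 years of death, Braak
  VI, CERAD frequent.

CASI latency uses 365.25-day years. Matching (`match_cases()`) links each
index case, processed in ascending `case_id` order, to a same-sex demented
case with severe ADNC (Braak VI, CERAD frequent), minimizing
lexicographically |Δ age at death|, then |Δ year of death|, then |Δ PMI|,
with residual ties broken by smallest `case_id`; matches are removed from
the pool (without replacement). Age and year are ranked hierarchically
because the selection narrative lists them together without a combined
metric; a lexicographic order is deterministic and auditable, and the
processing order must be fixed because without-replacement matching is
order dependent. These two conventions (age-then-year; ascending index
order) are this package's choices where the procedure was underspecified.
When both historic and re-evaluated Braak columns exist, callers choose
which column drives selection; both can be carried in the table.

## Ordinal scales and the summary score

The semi-quantitative scales bin field counts: pTau tangles per 10x field
(0; 1–2; 3–10; >10 → 0–3), amyloid-β plaques per 10x field (0; 1–4; 5–20;
>20 → 0–3), and pTDP-43 inclusions/neurites per 20x field (0; 1–2; 3–5;
6–10; 11–15; 16–20; >20 → 0–6). The published pTDP-43 scale overlaps at 15
("11–15" and "15–20"); `npq` resolves every shared bin edge to the lower
bin, one consistent rule applied to all scales. Fractional densities are
floored before binning. A count of zero always scores zero.

The summary neuropathology score sums four axes: ADNC (`Braak/2 + CERAD`,
0–6, half-integers allowed), microvascular brain injury (microinfarcts
capped at 3), Lewy body disease extent (0–3), and LATE-NC stage (0–3), for
a total of 0–15. `plot_score_composition()` draws the per-case stacked-bar
view ordered by total.

## Matched-pair statistics

Pairs are compared with exact tests: `wilcoxon_signed_rank()` for
continuous/ordinal variables and `mcnemar_exact()` for binary ones
(`paired_tests()` dispatches automatically). The Wilcoxon implementation
drops zero differences (the classical treatment — commercial packages
differ subtly here, a documented source of small p-value discrepancies),
mid-ranks ties, and computes the exact sign-flip distribution of the
positive-rank sum by dynamic programming over doubled ranks for up to 25
effective pairs (beyond that, a tie-corrected normal approximation with
continuity correction). Exactness matters at these sample sizes: with 7–14
pairs, asymptotic p-values are unreliable. Two-sided p-values double the
smaller tail and cap at 1, for both tests. No multiple-testing correction
is applied; per-region p-values are reported raw, and readers should judge
them accordingly. `chi_square_goodness_of_fit()` is the standard Pearson
test against fixed ratios with `df = k − 1`.

## Transgene segregation

`cross_model()` describes progeny of a parent homozygous for one transgene
and heterozygous for the transgene of interest: Mendelian expectation 25%
(+/+), 50% (+/−), 25% (−/−) for a single segregating element. Viability
selection multiplies each class by a relative viability and renormalizes
(`expected_proportions()`); synthetic lethality of the double homozygote is
the `viability = c(v, 1, 1)` case with small `v`. `test_segregation()`
compares observed counts to the *pre-selection* Mendelian ratios — that is
the published comparison, in which lethality appears as a significant
distortion. A two-class presence/absence collapse (3:1) supports
blind-scoring protocols. Fig-scale cohorts (~560 progeny) reject Mendelian
ratios at p < 0.0001 essentially always when the double-homozygote class
is nearly inviable.

## Synthetic data: what it does and does not emulate

The generators exist so every downstream metric can be tested against
planted ground truth without any external data.

* `render_ihc_image()` composites hematoxylin background and planted DAB
  objects (disks, ellipses, 1.5 μm-wide fibers — the fiber width
  guarantees roundness < 0.25, making them shape-filter violators by
  construction) through the forward Beer–Lambert model with the package's
  stain vectors, then adds Gaussian intensity noise (default SD 2 of 255,
  approximating scanner shot noise; the true noise process is
  undocumented). Objects may only overlap through declared bridges,
  because an undeclared overlap would make the planted ground truth
  ambiguous. What it does **not** emulate: tissue texture, nuclear
  morphology, pigment artifacts, uneven illumination, or chromatic
  aberration — so passing detector tests demonstrates correctness of the
  measurement chain, not robustness to real histological clutter.
* `simulate_cohort()` plants 14 resistant, 7 resilient, and a 60-case
  demented severe-ADNC matching pool in a 684-case cohort (the study-scale
  defaults), plus nine decoys each violating exactly one selection
  criterion, with the remainder constructed to satisfy neither predicate.
  Group-level shifts follow the reported directions: LATE-NC prevalence
  13/14 in the dementia pool vs 2/14 in resistant cases, more cortical
  pTau/pTDP-43, higher vascular scores, and ~110 g lower brain weight with
  dementia. Non-demented CASI trajectories are stable above the referral
  threshold (85); demented ones decline linearly through it and are
  censored at diagnosis. The planted effect sizes are generator settings,
  not estimates — recovery tests validate the pipeline's selectivity and
  power mechanics, not the biology.
* `simulate_progeny()` is a seeded multinomial draw from the
  post-selection genotype proportions.

All generators are pure functions of their parameters and seed.

## Numerical choices and degenerate inputs

* OD constants: `I0 = 255`, floor 1 intensity unit, cap `log10(255)`.
* Singular stain matrices error immediately, naming the vectors.
* Empty ROIs, zero-area ROIs, empty CASI histories, empty training sets,
  all-zero paired differences, and all-inviable cross models all raise
  explicit errors or flagged degenerate results (p = 1) rather than NaN.
* Watershed tolerance equals the merging threshold in intensity units of
  the smoothed map; fixtures probing split/merge behavior should use
  bridges wide relative to the smoothing radius, since a thin
  equal-density bridge already reads as a deep saddle after smoothing.
* Test and example problem sizes (e.g. 300–600 px canvases, 250–684-case
  cohorts, 300–400 simulation replicates) were chosen as the smallest
  sizes at which the checked properties are stable.

## Known limitations

* The declustering semantics and the intensity scale of the original
  commercial toolchain are not published; our interpretations are
  documented stand-ins, and absolute object counts may differ from that
  toolchain even when both are internally consistent.
* Whole-slide pyramidal formats are out of scope; inputs are plain
  RGB TIFF/PNG regions with a known pixel size.
* Stain vectors are taken as given; there is no automatic estimation.
* The cohort generator produces tabular structure, not images; the image
  and cohort halves of the pipeline are linked only through the burden
  metrics a user computes and attaches to the case table.
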