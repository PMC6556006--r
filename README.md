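# npq — quantitative neuropathology for brightfield IHC and aging cohorts

`npq` is an R toolkit for the quantitative side of dementia
neuropathology. It is written for neuropathologists and cohort analysts
who need to turn immunostained slide regions and autopsy case tables into
reproducible burden metrics, group selections, and matched-pair
statistics — in particular for studying **resistance** (reaching advanced
age without Alzheimer's disease neuropathologic change, ADNC) and
**resilience** (intact cognition despite severe ADNC).

## What it computes

**Stain quantification.** Brightfield absorbance is linear in stain on the
optical-density scale, `OD = -log10(I/255)`. With unit RGB OD vectors for
hematoxylin (0.67, 0.66, 0.339), DAB (0.311, 0.522, 0.794), and a residual
component (0.02, 0.999, 0.02), each pixel is a 3×3 linear unmixing problem
(`deconvolve()`). pTau burden in an ROI is reported as

```
OD × %Positive  =  mean OD over positive pixels × percent of ROI positive,
```

where a pixel is positive when its DAB pseudo-intensity falls below the
upper positive threshold (default 200 of 255).

**Inclusion counting.** pTDP-43 inclusions per mm² via Gaussian smoothing
(2 μm), intensity segmentation (threshold 220), watershed declustering
(saddle-depth merge threshold 2.5), and size/shape/intensity filters
(20–225 μm², roundness `4πA/P²` ≥ 0.25, elongation ≥ 0.1, mean intensity
≤ 200), with the positivity threshold calibratable from positive/negative
training slides by a 99th/60th percentile rule.

**Perforant-pathway synaptic integrity.** The relative immunointensity
ratio `RIR = (outer − blank)/(inner − blank)` of dentate-gyrus molecular
layer synaptophysin intensities.

**Cohort selection and matching.** Resistant (non-demented, CASI within 2
years of death, Braak ≤ III, CERAD none, age ≥ 85) and resilient
(non-demented, recent CASI, Braak VI, CERAD frequent) case selection, and
greedy one-to-one same-sex matching to demented severe-ADNC cases by age,
year of death, then post-mortem interval, without replacement.

**Scoring.** Semi-quantitative bins for pTau, amyloid-β, and pTDP-43 field
counts, and the 0–15 summary neuropathology score
`(Braak/2 + CERAD) + min(microinfarcts, 3) + LBD(0–3) + LATE-NC(0–3)`.

**Statistics.** Exact Wilcoxon matched-pairs signed-rank and exact McNemar
tests (enumeration-exact at cohort-study sample sizes), and chi-square
goodness of fit against Mendelian ratios (25/50/25) with genotype-specific
viability models for synthetic-lethality crosses.

**Synthetic data.** Seeded generators for IHC images with planted ground
truth, cohorts with planted group structure, and transgene-cross progeny
counts, so the whole pipeline is testable end to end without external data.

## Worked example

Select resistant cases from a simulated 684-autopsy cohort, match them to
demented severe-ADNC cases, and compare outcomes:

```r
library(npq)
sim <- simulate_cohort(seed = 42)                     # 684 cases, 14 planted resistant
resistant <- select_cases(sim$cohort, sim$casi, "resistant")
pairs <- match_cases(resistant[, names(sim$cohort)], sim$cohort)
head(pairs, 3)
#>   index_id match_id d_age d_year d_pmi sex
#> 1 C0001    C0064    0.200      0   8.2 F
#> 2 C0002    C0053    0.400      8  31.9 M
#> 3 C0003    C0028    0.200      2  24.2 F

paired_tests(paired_outcomes(pairs, sim$cohort,
                             c("brain_weight_g", "late_nc_present")))
#>   variable        n_pairs statistic  p_value method
#> 1 brain_weight_g       14        94 0.00671  Wilcoxon matched-pairs signed-rank (exact)
#> 2 late_nc_present      14         0 0.000244 McNemar exact
```

The resistant cases carry heavier brains (exact Wilcoxon p = 0.0067) and
almost no LATE-NC, while their dementia matches nearly all have it (exact
McNemar p = 0.00024) — the planted group structure, recovered by the
pipeline. Summary scores for the first pair show the same contrast
(`total` 1.5 vs 10 of 15):

```r
summary_score(sim$cohort[sim$cohort$case_id %in% c("C0001", "C0064"), ])
#>   case_id adnc_subscore uvbi_subscore lbd_subscore late_subscore total
#> 1 C0001             0.5             1            0             0   1.5
#> 2 C0064             6               1            1             2  10
```

On the image side, three 50 μm² disks planted at DAB OD 0.3 in a
150 × 150 μm field are counted at exactly 3 objects / 0.0225 mm²:

```r
img <- render_ihc_image(width_px = 300, height_px = 300, noise_sd = 0,
  objects = tibble::tibble(x = c(60, 150, 240), y = c(60, 150, 240),
                           shape = "disk", area_um2 = 50, dab_od = 0.3),
  seed = 7)
count_inclusions(img$image, roi_rect(0, 0, 300, 300))
#>   roi_id n_objects roi_area_mm2 objects_per_mm2
#> 1 roi_1          3       0.0225            133.
```

A command-line front end over the same functions is installed at
`inst/scripts/npq` (`quantify-tau`, `count-tdp43`, `rir`, `score`,
`segregation`, `simulate`).

See `vignettes/methods.Rmd` for the models, parameter meanings, and design
decisions.

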