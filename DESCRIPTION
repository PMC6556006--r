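Package: npq
Title: Quantitative Neuropathology of Brightfield IHC Slides and Aging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative neuropathology on brightfield
    immunohistochemistry images and community autopsy cohorts: Beer-Lambert
    color deconvolution of hematoxylin/DAB stains and positive-area burden
    metrics (OD x percent-positive), detection and counting of pTDP-43
    inclusions per square millimetre with shape filters and training-slide
    threshold calibration, the perforant-pathway synaptophysin relative
    immunointensity ratio, resistant/resilient case selection with
    one-to-one matching to dementia cases, ordinal and composite summary
    neuropathology scoring (ADNC, microvascular, Lewy body, LATE-NC axes),
    exact matched-pair statistics (Wilcoxon signed-rank, McNemar), and
    chi-square tests of Mendelian transgene segregation. Includes synthetic
    generators for IHC images with planted ground truth, autopsy cohorts
    with planted group structure, and transgene-cross progeny counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
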