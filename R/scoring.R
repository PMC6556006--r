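#' ADNC subscore
#'
#' Alzheimer's disease neuropathologic change axis of the summary
#' neuropathology score: Braak stage (expressed as a number 0-6) divided by
#' 2, plus the CERAD neuritic plaque score (0-3), so the maximum is 6.
#' Half-integer values are possible for odd Braak stages.
#'
#' @param braak Braak neurofibrillary tangle stage, integer 0-6
#'   (0, I-VI); vectorized.
#' @param cerad CERAD score: 0 none, 1 sparse, 2 moderate, 3 frequent.
#' @return Numeric subscore in `[0, 6]`.
#' @examples
#' adnc_subscore(6, 3)  # 6
#' adnc_subscore(3, 1)  # 2.5
#' @export
adnc_subscore <- function(braak, cerad) {
  .check_range(braak, 0, 6, "braak")
  .check_range(cerad, 0, 3, "cerad")
  braak / 2 + cerad
}

#' Microvascular brain injury subscore
#'
#' Number of chronic microinfarcts on the standardized screening sections,
#' capped at 3 (three or more microinfarcts score 3).
#'
#' @param n_microinfarcts Non-negative microinfarct count; vectorized.
#' @return Integer subscore in `[0, 3]`.
#' @export
uvbi_subscore <- function(n_microinfarcts) {
  if (any(n_microinfarcts < 0)) abort("Microinfarct count must be >= 0.")
  pmin(n_microinfarcts, 3)
}

.lbd_levels <- c("none", "brainstem", "limbic-amygdala", "neocortical")
.late_levels <- c("none", "amygdala", "hippocampal", "neocortical")

#' Lewy body disease subscore
#'
#' Ordinal extent of Lewy body disease: 0 none, 1 brainstem only, 2
#' limbic/amygdala-predominant, 3 neocortical (frontal or parietal).
#'
#' @param distribution Character vector with levels `"none"`,
#'   `"brainstem"`, `"limbic-amygdala"`, `"neocortical"`.
#' @return Integer subscore in `[0, 3]`.
#' @export
lbd_subscore <- function(distribution) {
  .ordinal_map(distribution, .lbd_levels, "LBD distribution")
}

#' LATE-NC subscore
#'
#' Ordinal stage of limbic-predominant age-related TDP-43 encephalopathy
#' neuropathologic change: 0 none, 1 amygdala only, 2 hippocampal, 3
#' neocortical (beyond medial temporal lobe).
#'
#' @param stage Character vector with levels `"none"`, `"amygdala"`,
#'   `"hippocampal"`, `"neocortical"`.
#' @return Integer subscore in `[0, 3]`.
#' @export
late_subscore <- function(stage) {
  .ordinal_map(stage, .late_levels, "LATE-NC stage")
}

.ordinal_map <- function(x, levels, what) {
  i <- match(x, levels)
  if (anyNA(i)) {
    abort(sprintf("Unknown %s label(s): %s (expected one of %s).",
                  what, paste(unique(x[is.na(i)]), collapse = ", "),
                  paste(levels, collapse = ", ")))
  }
  i - 1L
}

#' Summary neuropathology score
#'
#' Composite 0-15 burden score summing four axes: ADNC
#' (`braak/2 + cerad`, 0-6), microvascular brain injury (microinfarcts
#' capped at 3), Lewy body disease extent (0-3), and LATE-NC stage (0-3).
#' Accepts a case table and returns one row per case.
#'
#' @param cases Data frame with columns `braak_stage`, `cerad_score`,
#'   `n_microinfarcts`, `lbd_distribution`, `late_nc_stage` (and optionally
#'   `case_id`, carried through).
#' @return Tibble with `adnc_subscore`, `uvbi_subscore`, `lbd_subscore`,
#'   `late_subscore`, `total`.
#' @examples
#' summary_score(data.frame(braak_stage = 6, cerad_score = 3,
#'   n_microinfarcts = 3, lbd_distribution = "neocortical",
#'   late_nc_stage = "neocortical"))$total  # 15
#' @export
summary_score <- function(cases) {
  need <- c("braak_stage", "cerad_score", "n_microinfarcts",
            "lbd_distribution", "late_nc_stage")
  miss <- setdiff(need, names(cases))
  if (length(miss) > 0) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    adnc_subscore = adnc_subscore(cases$braak_stage, cases$cerad_score),
    uvbi_subscore = uvbi_subscore(cases$n_microinfarcts),
    lbd_subscore = lbd_subscore(cases$lbd_distribution),
    late_subscore = late_subscore(cases$late_nc_stage)
  )
  out$total <- out$adnc_subscore + out$uvbi_subscore +
    out$lbd_subscore + out$late_subscore
  if ("case_id" %in% names(cases)) {
    out <- dplyr::bind_cols(tibble(case_id = cases$case_id), out)
  }
  out
}

#' Semi-quantitative pTau score
#'
#' AT8 tangle burden per 10x field: 0 no tangles; 1 rare (< 3 per field);
#' 2 numerous (3-10); 3 extensive (> 10). Fractional counts are floored
#' before binning.
#'
#' @param tangles_per_10x Non-negative tangle count per 10x field;
#'   vectorized.
#' @return Integer score 0-3.
#' @export
bin_ptau <- function(tangles_per_10x) {
  .bin_counts(tangles_per_10x, upper = c(0, 2, 10), "tangle count")
}

#' Semi-quantitative amyloid-beta plaque score
#'
#' 6E10 plaque burden per 10x field: 0 none; 1 rare (< 5); 2 numerous
#' (5-20); 3 extensive (> 20).
#'
#' @param plaques_per_10x Non-negative plaque count per 10x field;
#'   vectorized.
#' @return Integer score 0-3.
#' @export
bin_abeta <- function(plaques_per_10x) {
  .bin_counts(plaques_per_10x, upper = c(0, 4, 20), "plaque count")
}

#' Semi-quantitative pTDP-43 density score
#'
#' Combined inclusions and neurites per 20x field: 0 none; 1 = 1-2;
#' 2 = 3-5; 3 = 6-10; 4 = 11-15; 5 = 16-20; 6 = > 20. A count of exactly
#' 15 falls in bin 4 (shared bin edges resolve to the lower bin throughout
#' the package).
#'
#' @param count_per_20x Non-negative inclusion/neurite count per 20x field;
#'   vectorized.
#' @return Integer score 0-6.
#' @export
bin_ptdp <- function(count_per_20x) {
  .bin_counts(count_per_20x, upper = c(0, 2, 5, 10, 15, 20),
              "inclusion/neurite count")
}

# Shared count-binning core: `upper[k]` is the largest count in bin k - 1;
# counts above the last edge get the top score.
.bin_counts <- function(count, upper, what) {
  if (any(count < 0) || anyNA(count)) {
    abort(sprintf("Negative or missing %s.", what))
  }
  count <- floor(count)
  findInterval(count, upper + 1L)
}
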