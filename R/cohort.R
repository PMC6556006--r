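#' Years between the last cognitive screen and death
#'
#' Latency from the most recent Cognitive Abilities Screening Instrument
#' (CASI) administration to death, in 365.25-day years. A short latency
#' gives confidence that the final cognitive status reflects the status at
#' death; selection below requires it to be at most two years.
#'
#' @param death_date Date of death (`Date` or coercible string).
#' @param casi_dates Vector of CASI administration dates for the case.
#' @return Latency in years (>= 0).
#' @examples
#' casi_latency(as.Date("2010-04-02"), as.Date("2009-12-31"))  # 92 days
#' @export
casi_latency <- function(death_date, casi_dates) {
  if (length(casi_dates) == 0L || all(is.na(casi_dates))) {
    abort("Empty CASI history: latency undefined.")
  }
  death_date <- as.Date(death_date)
  casi_dates <- as.Date(casi_dates)
  lat <- as.numeric(death_date - max(casi_dates, na.rm = TRUE)) / 365.25
  if (is.na(lat) || lat < 0) abort("Last CASI date is after the death date.")
  lat
}

# Per-case latency column from the long-format CASI table.
.latency_table <- function(cohort, casi) {
  stopifnot(all(c("case_id", "date") %in% names(casi)))
  casi %>%
    mutate(date = as.Date(.data$date)) %>%
    group_by(.data$case_id) %>%
    summarise(last_casi_date = max(.data$date), .groups = "drop") %>%
    left_join(cohort %>% select("case_id", "death_date"), by = "case_id") %>%
    mutate(casi_latency_years =
             as.numeric(as.Date(.data$death_date) - .data$last_casi_date) / 365.25)
}

#' Classify resistant cases
#'
#' A case is resistant to Alzheimer's disease neuropathologic change iff it
#' is non-demented with a CASI within two years of death, has Braak stage
#' III or lower and a CERAD score of none, and died at age 85 or older.
#'
#' @param cohort Case table with columns `case_id`, `dementia_status`
#'   (logical), `braak_stage` (0-6), `cerad_score` (0-3), `age_at_death`,
#'   `death_date`.
#' @param casi Long-format CASI table (`case_id`, `date`, `casi`).
#' @return Logical vector aligned with `cohort` rows.
#' @export
classify_resistant <- function(cohort, casi) {
  .check_selection_fields(cohort)
  lat <- .case_latency(cohort, casi)
  !cohort$dementia_status &
    !is.na(lat) & lat <= 2 &
    cohort$braak_stage <= 3 &
    cohort$cerad_score == 0 &
    cohort$age_at_death >= 85
}

#' Classify resilient cases
#'
#' A case is resilient iff it is non-demented with a CASI within two years
#' of death yet carries neuropathologically verified severe ADNC: Braak
#' stage VI and CERAD frequent.
#'
#' @inheritParams classify_resistant
#' @return Logical vector aligned with `cohort` rows.
#' @export
classify_resilient <- function(cohort, casi) {
  .check_selection_fields(cohort)
  lat <- .case_latency(cohort, casi)
  !cohort$dementia_status &
    !is.na(lat) & lat <= 2 &
    cohort$braak_stage == 6 &
    cohort$cerad_score == 3
}

.check_selection_fields <- function(cohort) {
  need <- c("case_id", "dementia_status", "braak_stage", "cerad_score",
            "age_at_death", "death_date")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("Missing cohort columns: ", paste(miss, collapse = ", ")))
  }
  if (anyNA(cohort$braak_stage) || anyNA(cohort$cerad_score)) {
    abort("Missing Braak stage or CERAD score; classification undefined.")
  }
}

.case_latency <- function(cohort, casi) {
  lt <- .latency_table(cohort, casi)
  lt$casi_latency_years[match(cohort$case_id, lt$case_id)]
}

#' Select resistant or resilient index cases
#'
#' @inheritParams classify_resistant
#' @param group `"resistant"` or `"resilient"`.
#' @return The selected rows of `cohort`, with a `casi_latency_years`
#'   column appended, as a tibble.
#' @export
select_cases <- function(cohort, casi, group = c("resistant", "resilient")) {
  group <- arg_match(group)
  keep <- switch(group,
                 resistant = classify_resistant(cohort, casi),
                 resilient = classify_resilient(cohort, casi))
  as_tibble(cohort[keep, , drop = FALSE]) %>%
    mutate(casi_latency_years = .case_latency(cohort, casi)[keep])
}

#' Match index cases to dementia cases with severe ADNC
#'
#' One-to-one, without-replacement greedy matching. Eligible pool members
#' are demented cases with Braak stage VI and CERAD frequent of the same
#' sex as the index case; the best match minimizes, lexicographically,
#' absolute differences in age at death, then year of death, then
#' post-mortem interval, with any remaining tie broken by smallest
#' `case_id`. Each selected match is removed from the pool before the next
#' index case (processed in ascending `case_id` order), making the result
#' deterministic and independent of pool row order.
#'
#' @param index_cases Data frame of index cases with `case_id`, `sex`,
#'   `age_at_death`, `year_of_death`, `pmi_hours`.
#' @param pool Data frame of candidate matches with the same columns plus
#'   `dementia_status`, `braak_stage`, `cerad_score`.
#' @param require_same_sex Require sex concordance (default TRUE).
#' @param enforce_pool_criteria Restrict the pool to demented Braak VI /
#'   CERAD frequent cases (default TRUE).
#' @return Tibble with one row per index case: `index_id`, `match_id`, the
#'   rank keys' absolute differences (`d_age`, `d_year`, `d_pmi`), and
#'   `sex`.
#' @export
match_cases <- function(index_cases, pool, require_same_sex = TRUE,
                        enforce_pool_criteria = TRUE) {
  if (enforce_pool_criteria) {
    pool <- pool %>%
      filter(.data$dementia_status, .data$braak_stage == 6,
             .data$cerad_score == 3)
  }
  pool <- pool %>% arrange(.data$case_id)
  idx <- index_cases %>% arrange(.data$case_id)
  used <- character(0)
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ic <- idx[i, ]
    cand <- pool %>% filter(!(.data$case_id %in% used))
    if (require_same_sex) cand <- cand %>% filter(.data$sex == ic$sex)
    if (nrow(cand) == 0L) {
      abort(sprintf("No eligible match remains for index case '%s'.", ic$case_id))
    }
    cand <- cand %>%
      mutate(d_age = abs(.data$age_at_death - ic$age_at_death),
             d_year = abs(.data$year_of_death - ic$year_of_death),
             d_pmi = abs(.data$pmi_hours - ic$pmi_hours)) %>%
      arrange(.data$d_age, .data$d_year, .data$d_pmi, .data$case_id)
    best <- cand[1, ]
    used <- c(used, best$case_id)
    rows[[i]] <- tibble(index_id = ic$case_id, match_id = best$case_id,
                        d_age = best$d_age, d_year = best$d_year,
                        d_pmi = best$d_pmi, sex = ic$sex)
  }
  bind_rows(rows)
}

#' Assemble per-pair outcome vectors
#'
#' Joins index and matched cases' values of the requested variables into a
#' paired long table ready for [paired_tests()].
#'
#' @param pairs Output of [match_cases()].
#' @param cohort Full case table containing `case_id` and the variables.
#' @param vars Character vector of cohort column names to pair.
#' @return Tibble with columns `variable`, `index_id`, `match_id`,
#'   `index_value`, `match_value`.
#' @export
paired_outcomes <- function(pairs, cohort, vars) {
  miss <- setdiff(vars, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("Variables not in cohort: ", paste(miss, collapse = ", ")))
  }
  purrr::map(vars, function(v) {
    tibble(variable = v,
           index_id = pairs$index_id,
           match_id = pairs$match_id,
           index_value = cohort[[v]][match(pairs$index_id, cohort$case_id)],
           match_value = cohort[[v]][match(pairs$match_id, cohort$case_id)])
  }) %>% bind_rows()
}

.check_range <- function(x, lo, hi, what) {
  if (anyNA(x) || any(x < lo | x > hi)) {
    abort(sprintf("`%s` must lie in [%s, %s].", what, lo, hi))
  }
}
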