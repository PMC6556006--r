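#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test for paired samples. Zero differences are
#' dropped (the classical treatment); tied absolute differences receive
#' mid-ranks. For `n <= exact_max_n` effective pairs the null distribution
#' of the positive-rank sum is computed exactly over all `2^n` sign
#' assignments (by dynamic programming over doubled ranks, which handles
#' mid-ranks without approximation); the two-sided p doubles the smaller
#' tail and caps at 1. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param index_values,match_values Paired numeric vectors, or a single
#'   vector of differences in `index_values` with `match_values = 0`.
#' @param exact_max_n Largest effective n for which the exact distribution
#'   is enumerated (default 25).
#' @return An `npq_htest` object; see [tidy.npq_htest()]. Fields:
#'   `statistic` (positive-rank sum W), `p_value`, `n` (non-zero pairs),
#'   `exact`, `degenerate` (all differences zero), `method`.
#' @examples
#' tidy(wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)))
#' @export
wilcoxon_signed_rank <- function(index_values, match_values = 0,
                                 exact_max_n = 25) {
  d <- index_values - match_values
  if (anyNA(d)) abort("Missing values in paired differences.")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(.htest(statistic = NA_real_, p_value = 1, n = 0L, exact = TRUE,
                  degenerate = TRUE,
                  method = "Wilcoxon matched-pairs signed-rank (exact)"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- .wilcoxon_exact_p(r, w)
    method <- "Wilcoxon matched-pairs signed-rank (exact)"
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon matched-pairs signed-rank (normal approximation)"
    exact <- FALSE
  }
  .htest(statistic = w, p_value = p, n = n, exact = exact,
         degenerate = FALSE, method = method)
}

# Exact two-sided p for rank vector r and observed positive-rank sum w.
# Doubled ranks are integers even under mid-ranking; the count vector over
# achievable doubled sums is built by the standard subset-sum recursion.
.wilcoxon_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  s <- sum(r2)
  counts <- numeric(s + 1L)
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(s + 1L - rk)])
    counts <- counts + shifted
  }
  total <- sum(counts)             # 2^n
  w2 <- as.integer(round(2 * w))
  lo <- sum(counts[seq_len(w2 + 1L)]) / total          # P(W <= w)
  hi <- sum(counts[(w2 + 1L):(s + 1L)]) / total        # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Exact McNemar test for paired binary outcomes
#'
#' Conditional on the number of discordant pairs `b + c`, the index-only
#' positive count is Binomial(b + c, 1/2) under the null; the two-sided
#' exact p doubles the smaller tail, `min(1, 2 P(X <= min(b, c)))`.
#'
#' @param b Discordant pairs positive in the index case only.
#' @param c Discordant pairs positive in the matched case only.
#' @return An `npq_htest` object with `statistic = b` and attributes as in
#'   [wilcoxon_signed_rank()].
#' @examples
#' tidy(mcnemar_exact(6, 0))  # p = 2 * (1/2)^6
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    abort("`b` and `c` must be non-negative integers.")
  }
  n <- b + c
  if (n == 0) {
    return(.htest(statistic = NA_real_, p_value = 1, n = 0L, exact = TRUE,
                  degenerate = TRUE, method = "McNemar exact"))
  }
  p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
  .htest(statistic = b, p_value = p, n = as.integer(n), exact = TRUE,
         degenerate = FALSE, method = "McNemar exact")
}

#' Chi-square goodness of fit against fixed ratios
#'
#' Pearson chi-square of observed counts against expected proportions, as
#' used to compare transgene-cross progeny classes with Mendelian ratios.
#'
#' @param observed_counts Non-negative counts summing to > 0.
#' @param expected_ratios Expected proportions, same length, summing to 1.
#' @return An `npq_htest` with `statistic` (chi-square), `df`, `p_value`.
#' @examples
#' tidy(chi_square_goodness_of_fit(c(90, 210, 100), c(1, 2, 1) / 4))
#' @export
chi_square_goodness_of_fit <- function(observed_counts, expected_ratios) {
  if (length(observed_counts) != length(expected_ratios)) {
    abort("Counts and ratios must have the same length.")
  }
  if (any(observed_counts < 0) || sum(observed_counts) <= 0) {
    abort("Observed counts must be non-negative and sum to > 0.")
  }
  if (abs(sum(expected_ratios) - 1) > 1e-8) {
    abort("Expected ratios must sum to 1.")
  }
  e <- sum(observed_counts) * expected_ratios
  if (any(e == 0)) abort("Expected count of zero in some class; chi-square undefined.")
  chi2 <- sum((observed_counts - e)^2 / e)
  df <- length(observed_counts) - 1L
  out <- .htest(statistic = chi2, p_value = pchisq(chi2, df, lower.tail = FALSE),
                n = as.integer(sum(observed_counts)), exact = FALSE,
                degenerate = FALSE, method = "Chi-square goodness of fit")
  out$df <- df
  out
}

.htest <- function(statistic, p_value, n, exact, degenerate, method) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 exact = exact, degenerate = degenerate, method = method),
            class = "npq_htest")
}

#' @export
print.npq_htest <- function(x, ...) {
  cat(sprintf("<npq_htest> %s\n  statistic = %s, n = %d, p = %.5g%s\n",
              x$method,
              ifelse(is.na(x$statistic), "NA", format(x$statistic)),
              x$n, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Tidy an npq hypothesis test
#'
#' @param x An `npq_htest` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `n`, `exact`,
#'   `degenerate`, `method` (plus `df` for chi-square tests).
#' @method tidy npq_htest
#' @export
tidy.npq_htest <- function(x, ...) {
  out <- tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                exact = x$exact, degenerate = x$degenerate, method = x$method)
  if (!is.null(x$df)) out <- mutate(out, df = x$df, .after = "statistic")
  out
}

#' @rdname tidy.npq_htest
#' @method glance npq_htest
#' @export
glance.npq_htest <- function(x, ...) tidy(x, ...)

#' Run paired tests across variables
#'
#' Applies the exact McNemar test to binary variables and the Wilcoxon
#' matched-pairs signed-rank test to continuous or ordinal variables, one
#' variable at a time, mirroring matched-pair cohort analyses. No
#' multiple-testing correction is applied; p-values are reported raw.
#'
#' @param outcomes Long table from [paired_outcomes()] with columns
#'   `variable`, `index_value`, `match_value`.
#' @return Tibble with one row per variable: `variable`, `n_pairs`,
#'   `statistic`, `p_value`, `method`.
#' @export
paired_tests <- function(outcomes) {
  outcomes %>%
    group_by(.data$variable) %>%
    dplyr::group_modify(function(g, key) {
      iv <- g$index_value; mv <- g$match_value
      binary <- all(c(iv, mv) %in% c(0, 1, TRUE, FALSE))
      ht <- if (binary) {
        mcnemar_exact(sum(iv == 1 & mv == 0), sum(iv == 0 & mv == 1))
      } else {
        wilcoxon_signed_rank(as.numeric(iv), as.numeric(mv))
      }
      tibble(n_pairs = length(iv), statistic = ht$statistic,
             p_value = ht$p_value, method = ht$method)
    }) %>%
    ungroup()
}
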