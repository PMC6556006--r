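test_that("exact Wilcoxon p matches hand-derived small cases", {
  ht <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(ht$statistic, 15)
  expect_equal(ht$p_value, 2 / 32)
  # perfect symmetry with a mid-rank tie
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
  # all-zero differences: degenerate, p defined as 1
  ht0 <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(ht0$degenerate)
  expect_equal(ht0$p_value, 1)
})

test_that("exact Wilcoxon agrees with the 2^n enumeration oracle", {
  set.seed(31)
  for (n in c(3, 5, 7, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, sd = 3), 1)
      d[d == 0] <- 0.5
      if (rep == 3) d[2] <- d[1]          # force tied |differences|
      ht <- wilcoxon_signed_rank(d)
      expect_equal(ht$p_value, wilcoxon_enumeration_oracle(d),
                   tolerance = 1e-12, label = paste("n =", n))
    }
  }
})

test_that("exact Wilcoxon matches stats::wilcox.test without ties", {
  set.seed(32)
  for (n in c(6, 12, 20)) {
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact Wilcoxon p is invariant under sign/order-preserving transforms", {
  set.seed(33)
  d <- c(0.4, -1.2, 2.5, -0.1, 3.3, 1.8, -2.2)
  p0 <- wilcoxon_signed_rank(d)$p_value
  mono <- function(x) sign(x) * (abs(x)^1.5 + 2 * abs(x))  # odd, increasing
  expect_equal(wilcoxon_signed_rank(mono(d))$p_value, p0)
  expect_equal(wilcoxon_signed_rank(3 * d)$p_value, p0)
})

test_that("large-sample Wilcoxon falls back to the tie-corrected normal", {
  set.seed(34)
  x <- rnorm(40, mean = 0.4)
  ht <- wilcoxon_signed_rank(x, exact_max_n = 25)
  expect_false(ht$exact)
  ref <- stats::wilcox.test(x, exact = FALSE, correct = TRUE)
  expect_equal(ht$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("exact McNemar matches the binomial tail construction", {
  expect_equal(mcnemar_exact(6, 0)$p_value, 2 * 0.5^6)
  expect_equal(mcnemar_exact(3, 3)$p_value, 1)
  expect_true(mcnemar_exact(0, 0)$degenerate)
  for (b in 0:12) {
    for (c in 0:(12 - b)) {
      expect_equal(mcnemar_exact(b, c)$p_value,
                   mcnemar_enumeration_oracle(b, c),
                   label = sprintf("b=%d c=%d", b, c))
      expect_equal(mcnemar_exact(b, c)$p_value, mcnemar_exact(c, b)$p_value)
    }
  }
})

test_that("McNemar p decreases in |b - c| at fixed discordant total", {
  for (n in c(6, 11)) {
    ps <- vapply(0:floor(n / 2), function(m) mcnemar_exact(m, n - m)$p_value, 0)
    expect_true(all(diff(ps) >= 0))  # more balance -> larger p
  }
})

test_that("chi-square goodness of fit matches hand computation and chisq.test", {
  perfect <- chi_square_goodness_of_fit(c(25, 50, 25), c(1, 2, 1) / 4)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  expect_equal(chi_square_goodness_of_fit(c(100, 200, 100),
                                          c(1, 2, 1) / 4)$statistic, 0)
  # (90-100)^2/100 + (210-200)^2/200 + 0 = 1.5
  hand <- chi_square_goodness_of_fit(c(90, 210, 100), c(1, 2, 1) / 4)
  expect_equal(hand$statistic, 1.5)
  expect_equal(hand$df, 2)
  ref <- stats::chisq.test(c(90, 210, 100), p = c(1, 2, 1) / 4)
  expect_equal(hand$statistic, unname(ref$statistic))
  expect_equal(hand$p_value, unname(ref$p.value))
  expect_error(chi_square_goodness_of_fit(c(5, 5), c(1, 0)), "zero")
})

test_that("paired_tests dispatches McNemar for binary and Wilcoxon otherwise", {
  outcomes <- dplyr::bind_rows(
    tibble::tibble(variable = "late_nc_present",
                   index_value = c(0, 0, 1, 0, 0), match_value = c(1, 1, 1, 1, 0)),
    tibble::tibble(variable = "brain_weight_g",
                   index_value = c(1250, 1300, 1180, 1290, 1310),
                   match_value = c(1100, 1120, 1150, 1080, 1090)))
  res <- paired_tests(outcomes)
  expect_equal(nrow(res), 2)
  expect_match(res$method[res$variable == "late_nc_present"], "McNemar")
  expect_match(res$method[res$variable == "brain_weight_g"], "Wilcoxon")
  expect_equal(res$p_value[res$variable == "brain_weight_g"], 2 / 32)
})

test_that("tidy and glance return one-row summaries", {
  td <- tidy(wilcoxon_signed_rank(c(1, 2, 3)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p_value", "n", "exact", "degenerate",
                     "method"))
  gc <- glance(chi_square_goodness_of_fit(c(10, 20), c(0.5, 0.5)))
  expect_true("df" %in% names(gc))
})
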