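# Shared fixture builders. Everything is generated in code; no binary data.

# Forward Beer-Lambert synthesis of an RGB image from per-stain OD maps,
# independent of render_ihc_image (used as the deconvolution oracle).
synth_rgb <- function(od_hem, od_dab, model = stain_model(),
                      pixel_size_um = 0.5) {
  v <- model$vectors
  h <- nrow(od_hem); w <- ncol(od_hem)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- 255 * 10^-(od_hem * v["hematoxylin", ch] +
                                od_dab * v["dab", ch])
  }
  rgb_image(img, pixel_size_um = pixel_size_um)
}

# DAB pseudo-intensity map of an image under the default stain model.
dab_intensity <- function(image, model = stain_model()) {
  stain_to_intensity(deconvolve(rgb_to_od(image), model)$dab)
}

# Exhaustive 2^n sign-flip oracle for the exact Wilcoxon signed-rank p.
wilcoxon_enumeration_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Enumeration oracle for the exact McNemar p: all 2^(b+c) equally likely
# direction assignments of the discordant pairs.
mcnemar_enumeration_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  ks <- 0:n
  probs <- choose(n, ks) / 2^n
  m <- min(b, c)
  min(1, 2 * sum(probs[ks <= m]))
}

# Minimal valid case table row(s) for the scoring/selection functions.
make_cases <- function(n = 1, braak = 0, cerad = 0, cmi = 0,
                       lbd = "none", late = "none") {
  tibble::tibble(
    case_id = sprintf("X%03d", seq_len(n)),
    braak_stage = rep_len(braak, n), cerad_score = rep_len(cerad, n),
    n_microinfarcts = rep_len(cmi, n),
    lbd_distribution = rep_len(lbd, n), late_nc_stage = rep_len(late, n))
}

# Small hand-built cohort for selection/matching unit tests.
make_mini_cohort <- function() {
  death <- as.Date("2010-06-01")
  cohort <- tibble::tibble(
    case_id = sprintf("C%02d", 1:8),
    sex = c("F", "F", "M", "F", "F", "F", "M", "F"),
    age_at_death = c(90, 80, 92, 86, 91, 89, 92, 88),
    year_of_death = c(2010, 2010, 2011, 2009, 2010, 2010, 2011, 2008),
    death_date = death,
    pmi_hours = c(6, 7, 10, 12, 5, 30, 9, 8),
    dementia_status = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    braak_stage = c(2, 2, 6, 6, 6, 6, 6, 6),
    cerad_score = c(0, 0, 3, 3, 3, 3, 3, 3))
  casi <- tibble::tibble(
    case_id = cohort$case_id,
    date = death - round(c(0.5, 0.5, 1, 2.5, 4, 4, 4, 4) * 365.25),
    casi = c(95, 96, 94, 93, 80, 78, 82, 75))
  list(cohort = cohort, casi = casi)
}
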