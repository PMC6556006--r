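#' Transgene cross model
#'
#' Describes the F1 self-cross of an animal homozygous for one transgene
#' and heterozygous for the transgene of interest. A single segregating
#' element yields expected progeny ratios 25% (+/+), 50% (+/-), 25% (-/-);
#' genotype-specific relative viabilities model synthetic lethality (e.g.
#' joint hTau/hTDP-43 homozygosity) as reduced survival of a class.
#'
#' @param mendelian_ratios Expected genotype proportions at fertilization,
#'   in the order (+/+, +/-, -/-); must sum to 1.
#' @param viability Relative viability of each genotype class in `[0, 1]`.
#' @param genotypes Class labels.
#' @return A list of class `npq_cross_model`.
#' @export
cross_model <- function(mendelian_ratios = c(0.25, 0.5, 0.25),
                        viability = c(1, 1, 1),
                        genotypes = c("+/+", "+/-", "-/-")) {
  if (length(mendelian_ratios) != length(viability) ||
      length(genotypes) != length(viability)) {
    abort("Ratios, viabilities and genotype labels must align.")
  }
  if (abs(sum(mendelian_ratios) - 1) > 1e-8 || any(mendelian_ratios < 0)) {
    abort("Mendelian ratios must be non-negative and sum to 1.")
  }
  if (any(viability < 0 | viability > 1)) {
    abort("Viabilities must lie in [0, 1].")
  }
  structure(list(mendelian_ratios = setNames(mendelian_ratios, genotypes),
                 viability = setNames(viability, genotypes),
                 genotypes = genotypes),
            class = "npq_cross_model")
}

#' @export
print.npq_cross_model <- function(x, ...) {
  cat("<npq_cross_model>\n")
  print(rbind(mendelian = x$mendelian_ratios, viability = x$viability))
  invisible(x)
}

#' Expected progeny proportions after viability selection
#'
#' Proportions proportional to `mendelian_ratio * viability`, renormalized
#' over surviving classes.
#'
#' @param model A [cross_model()].
#' @return Named numeric vector summing to 1.
#' @examples
#' expected_proportions(cross_model())                         # 1/4, 1/2, 1/4
#' expected_proportions(cross_model(viability = c(0, 1, 1)))   # 0, 2/3, 1/3
#' @export
expected_proportions <- function(model) {
  stopifnot(inherits(model, "npq_cross_model"))
  w <- model$mendelian_ratios * model$viability
  if (sum(w) == 0) abort("All genotype classes have zero viability.")
  w / sum(w)
}

#' Test observed progeny counts against Mendelian expectation
#'
#' Chi-square goodness of fit of observed genotype counts against the
#' model's pre-selection Mendelian ratios (the published comparison:
#' survival distortion shows up as departure from 25/50/25).
#'
#' @param counts Observed counts per genotype class, aligned with the
#'   model's classes.
#' @param model A [cross_model()].
#' @return An `npq_htest` (see [chi_square_goodness_of_fit()]).
#' @export
test_segregation <- function(counts, model = cross_model()) {
  stopifnot(inherits(model, "npq_cross_model"))
  if (sum(counts) <= 0) abort("Total progeny count must be positive.")
  chi_square_goodness_of_fit(counts, unname(model$mendelian_ratios))
}

#' Collapse a cross model to transgene presence/absence
#'
#' Two-class variant for blind scoring protocols that only record whether
#' the transgene is present: expected 3/4 present (+/+ or +/-) vs 1/4
#' absent.
#'
#' @param model A three-class [cross_model()].
#' @return A two-class `npq_cross_model` with classes `present`/`absent`.
#' @export
collapse_to_presence <- function(model = cross_model()) {
  stopifnot(inherits(model, "npq_cross_model"), length(model$genotypes) == 3L)
  r <- unname(model$mendelian_ratios)
  v <- unname(model$viability)
  pres <- r[1] + r[2]
  cross_model(mendelian_ratios = c(pres, r[3]),
              viability = c(if (pres > 0) (r[1] * v[1] + r[2] * v[2]) / pres else 0,
                            v[3]),
              genotypes = c("present", "absent"))
}
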