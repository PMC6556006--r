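#' Relative immunointensity ratio (RIR)
#'
#' Perforant-pathway synaptic integrity metric: mean 8-bit pixel intensities
#' of the outer and inner molecular layers of the dentate gyrus, normalized
#' per slide to a blank region, combined as
#' `(outer - blank) / (inner - blank)`. Symmetric staining gives 1; the
#' ratio falls toward 0 as outer-molecular-layer staining is preferentially
#' lost.
#'
#' @param outer_mean_intensity,inner_mean_intensity,blank_mean_intensity
#'   Mean pixel intensities on the 0-255 scale; vectorized (one element per
#'   case/slide). The blank region is the brightest of the three in a valid
#'   stained section.
#' @return Numeric vector of ratios.
#' @examples
#' compute_rir(100, 100, 200)      # 1
#' compute_rir(150, 50, 200)       # 1/3
#' @export
compute_rir <- function(outer_mean_intensity, inner_mean_intensity,
                        blank_mean_intensity) {
  v <- c(outer_mean_intensity, inner_mean_intensity, blank_mean_intensity)
  if (any(v < 0 | v > 255)) abort("Intensities must lie in [0, 255].")
  if (any(inner_mean_intensity == blank_mean_intensity)) {
    abort("Inner-layer intensity equals blank: no inner staining, RIR undefined.")
  }
  (outer_mean_intensity - blank_mean_intensity) /
    (inner_mean_intensity - blank_mean_intensity)
}

#' Measure the RIR from an image and three layer ROIs
#'
#' Mean luminance is measured over each ROI of the raw (undeconvolved)
#' image, as in manual densitometry practice, then combined with
#' [compute_rir()].
#'
#' @param image An [rgb_image()] of a synaptophysin-stained hippocampal
#'   section.
#' @param outer_roi,inner_roi,blank_roi [roi_polygon()] regions for the
#'   outer molecular layer, inner molecular layer, and a blank area.
#' @return One-row tibble: `outer_mean_intensity`, `inner_mean_intensity`,
#'   `blank_mean_intensity`, `rir`.
#' @export
measure_rir <- function(image, outer_roi, inner_roi, blank_roi) {
  lum <- luminance(image)
  m <- function(roi) mean(lum[roi_mask(roi, dim(lum))])
  o <- m(outer_roi); i <- m(inner_roi); b <- m(blank_roi)
  tibble(outer_mean_intensity = o,
         inner_mean_intensity = i,
         blank_mean_intensity = b,
         rir = compute_rir(o, i, b))
}
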