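#' Stain color model for brightfield color deconvolution
#'
#' Holds the RGB optical-density vectors of the two chromogens and a residual
#' component, each normalized to unit length, together with the 3x3 unmixing
#' matrix they induce. The defaults are vectors measured on
#' hematoxylin/DAB-stained human brain sections: hematoxylin
#' (0.67, 0.66, 0.339), DAB (0.311, 0.522, 0.794), and a residual component
#' (0.02, 0.999, 0.02) that absorbs off-axis signal and sharpens the digital
#' separation of the two true stains.
#'
#' @param hematoxylin,dab,residual Length-3 numeric RGB optical-density
#'   vectors (any positive scale; stored unit-normalized).
#' @return An object of class `npq_stain_model` with elements `vectors`
#'   (3x3 matrix, one row per stain) and `unmix` (its inverse).
#' @examples
#' m <- stain_model()
#' rowSums(m$vectors^2)  # unit rows
#' @export
stain_model <- function(hematoxylin = c(0.67, 0.66, 0.339),
                        dab = c(0.311, 0.522, 0.794),
                        residual = c(0.02, 0.999, 0.02)) {
  v <- rbind(hematoxylin = hematoxylin, dab = dab, residual = residual)
  if (!is.numeric(v) || ncol(v) != 3L || anyNA(v)) {
    abort("Each stain vector must be a numeric RGB triple.")
  }
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) abort("Stain vectors must be non-zero.")
  v <- v / nrm
  colnames(v) <- c("R", "G", "B")
  unmix <- tryCatch(solve(t(v)), error = function(e) NULL)
  if (is.null(unmix) || !all(is.finite(unmix))) {
    abort(paste0(
      "Singular stain matrix; the vectors do not span RGB space: ",
      paste(apply(round(v, 3), 1, function(r) paste0("(", paste(r, collapse = ", "), ")")),
            collapse = ", ")))
  }
  structure(list(vectors = v, unmix = unmix), class = "npq_stain_model")
}

#' @export
print.npq_stain_model <- function(x, ...) {
  cat("<npq_stain_model> unit RGB optical-density vectors\n")
  print(round(x$vectors, 4))
  invisible(x)
}

# Beer-Lambert constants: 8-bit incident intensity, 1-unit floor so that the
# optical density is capped at log10(255) for saturated (zero) pixels.
.OD_I0 <- 255
.OD_EPS <- 1
.OD_MAX <- log10(255)

#' Convert 8-bit intensities to optical density
#'
#' Beer-Lambert transform `OD = -log10(max(I, 1) / 255)` applied per channel.
#' A blank (255) pixel has OD 0; a fully saturated (0) pixel is clamped to
#' `log10(255)`, about 2.407.
#'
#' @param image An [rgb_image()], or a numeric array/matrix of intensities on
#'   the 0-255 scale.
#' @return Array/matrix of the same shape holding optical densities; carries
#'   the source's `pixel_size_um` attribute when available.
#' @examples
#' rgb_to_od(255)  # 0
#' rgb_to_od(25.5) # 1
#' @export
rgb_to_od <- function(image) {
  ps <- NULL
  if (inherits(image, "npq_image")) {
    ps <- image$pixel_size_um
    image <- image$pixels
  } else {
    ps <- attr(image, "pixel_size_um")
  }
  od <- -log10(pmax(image, .OD_EPS) / .OD_I0)
  od <- pmin(od, .OD_MAX)
  attr(od, "pixel_size_um") <- ps
  od
}

#' Convert a single-stain optical-density map to pseudo-intensity
#'
#' Inverse Beer-Lambert on one channel: `I = 255 * 10^(-OD)`. This is the
#' scale on which the segmentation (220) and upper-positive (200) thresholds
#' of the slide-analysis workflows are expressed.
#'
#' @param od_map Numeric matrix (or array) of non-negative optical densities.
#' @return Pseudo-intensities on the 0-255 scale, same shape, preserving any
#'   `pixel_size_um` attribute.
#' @export
stain_to_intensity <- function(od_map) {
  if (min(od_map) < 0) abort("Optical densities must be non-negative.")
  out <- .OD_I0 * 10^(-od_map)
  attr(out, "pixel_size_um") <- attr(od_map, "pixel_size_um")
  out
}

#' Unmix an optical-density image into per-stain maps
#'
#' Solves the per-pixel 3-stain Beer-Lambert system `OD_rgb = A^T c` where the
#' rows of `A` are the model's unit stain vectors, then clips negative
#' concentrations to zero (standard practice for off-model pixels).
#'
#' @param od An `H x W x 3` optical-density array from [rgb_to_od()].
#' @param model A [stain_model()].
#' @return Named list of `H x W` matrices `hematoxylin`, `dab`, `residual`
#'   (per-pixel stain OD, >= 0), each carrying the source `pixel_size_um`
#'   attribute.
#' @examples
#' img <- rgb_image(array(255, dim = c(4, 4, 3)))
#' maps <- deconvolve(rgb_to_od(img), stain_model())
#' max(abs(maps$dab))  # 0 on a blank image
#' @export
deconvolve <- function(od, model = stain_model()) {
  stopifnot(inherits(model, "npq_stain_model"))
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    abort("`od` must be an H x W x 3 optical-density array.")
  }
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)            # pixels x RGB
  conc <- flat %*% t(model$unmix)          # pixels x stains
  conc[conc < 0] <- 0
  ps <- attr(od, "pixel_size_um")
  out <- lapply(seq_len(3L), function(k) {
    m <- matrix(conc[, k], nrow = d[1], ncol = d[2])
    attr(m, "pixel_size_um") <- ps
    m
  })
  names(out) <- rownames(model$vectors)
  out
}

#' Positive-area burden analysis of a DAB channel
#'
#' Counts ROI pixels whose deconvolved DAB pseudo-intensity is darker than
#' the upper positive threshold and reports the percent-positive area, the
#' mean optical density over positive pixels, and their product
#' (`OD x %Positive`), the weighted burden metric used for pTau.
#'
#' @param dab_intensity_map `H x W` DAB pseudo-intensity matrix (0-255), as
#'   from `stain_to_intensity(deconvolve(...)$dab)`.
#' @param roi An [roi_polygon()].
#' @param threshold Upper positive intensity threshold on the 0-255 scale
#'   (default 200): a pixel is positive iff its intensity is strictly below
#'   it, i.e. iff it is stained darker than the cutoff.
#' @param pixel_size_um Pixel size; taken from the map attribute if absent.
#' @return One-row tibble: `n_pixels`, `n_positive`, `percent_positive`,
#'   `avg_positive_od`, `od_weighted_metric`, `roi_area_mm2`.
#' @export
area_analysis <- function(dab_intensity_map, roi, threshold = 200,
                          pixel_size_um = NULL) {
  ps <- .pixel_size(dab_intensity_map, pixel_size_um)
  mask <- roi_mask(roi, dim(dab_intensity_map))
  n <- sum(mask)
  if (n == 0L) abort("ROI contains no pixels.")
  vals <- dab_intensity_map[mask]
  pos <- vals < threshold
  pct <- 100 * sum(pos) / n
  avg_od <- if (any(pos)) mean(-log10(pmax(vals[pos], .OD_EPS) / .OD_I0)) else 0
  tibble(
    n_pixels = n,
    n_positive = sum(pos),
    percent_positive = pct,
    avg_positive_od = avg_od,
    od_weighted_metric = avg_od * pct,
    roi_area_mm2 = n * ps^2 / 1e6
  )
}

#' Limbic-predominant subtype call from regional tau burden
#'
#' Classifies a case as limbic-predominant when the hippocampus / middle
#' frontal gyrus tau optical-density ratio strictly exceeds the cutoff
#' (default 1.5).
#'
#' @param hippocampus_metric,mfg_metric Non-negative regional tau burden
#'   metrics (e.g. `od_weighted_metric`); vectorized.
#' @param ratio_cutoff Ratio above which the case is limbic-predominant.
#' @return Character vector: `"limbic-predominant"` or
#'   `"not limbic-predominant"`.
#' @export
tau_subtype_ratio <- function(hippocampus_metric, mfg_metric,
                              ratio_cutoff = 1.5) {
  if (any(hippocampus_metric < 0) || any(mfg_metric < 0)) {
    abort("Burden metrics must be non-negative.")
  }
  if (any(mfg_metric == 0)) {
    abort("MFG metric of 0: hippocampus/MFG ratio is undefined.")
  }
  ifelse(hippocampus_metric / mfg_metric > ratio_cutoff,
         "limbic-predominant", "not limbic-predominant")
}
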