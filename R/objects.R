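#' Parameters for inclusion detection
#'
#' Defaults are the calibrated slide-analysis settings for counting
#' pTDP-43-positive inclusions: 2 um smoothing radius, declustering merge
#' threshold 2.5 (intensity units of saddle depth), segmentation intensity
#' threshold 220, size window 20-225 um^2, minimum roundness 0.25, minimum
#' elongation 0.1, and upper positive intensity threshold 200.
#'
#' @param smoothing_radius_um Gaussian smoothing sigma in micrometres.
#' @param merging_threshold Saddle depth (intensity units) below which two
#'   touching watershed basins are merged into one object.
#' @param segmentation_intensity_threshold Pixels with smoothed DAB
#'   pseudo-intensity strictly below this value form candidate objects.
#' @param min_area_um2,max_area_um2 Object size window in um^2.
#' @param min_roundness Minimum `4*pi*A/P^2` (Crofton perimeter).
#' @param min_elongation Minimum minor/major axis ratio of the best-fit
#'   ellipse.
#' @param upper_positive_intensity_threshold Objects with mean DAB intensity
#'   above this value are rejected as too faint to be positive.
#' @return A list of class `npq_detection_params`.
#' @export
detection_params <- function(smoothing_radius_um = 2,
                             merging_threshold = 2.5,
                             segmentation_intensity_threshold = 220,
                             min_area_um2 = 20,
                             max_area_um2 = 225,
                             min_roundness = 0.25,
                             min_elongation = 0.1,
                             upper_positive_intensity_threshold = 200) {
  p <- list(smoothing_radius_um = smoothing_radius_um,
            merging_threshold = merging_threshold,
            segmentation_intensity_threshold = segmentation_intensity_threshold,
            min_area_um2 = min_area_um2,
            max_area_um2 = max_area_um2,
            min_roundness = min_roundness,
            min_elongation = min_elongation,
            upper_positive_intensity_threshold = upper_positive_intensity_threshold)
  if (!(p$min_area_um2 > 0 && p$min_area_um2 < p$max_area_um2)) {
    abort("Require 0 < min_area_um2 < max_area_um2.")
  }
  if (p$segmentation_intensity_threshold < 0 || p$segmentation_intensity_threshold > 255 ||
      p$upper_positive_intensity_threshold < 0 || p$upper_positive_intensity_threshold > 255) {
    abort("Intensity thresholds must lie in [0, 255].")
  }
  if (p$min_roundness < 0 || p$min_roundness > 1 ||
      p$min_elongation < 0 || p$min_elongation > 1) {
    abort("min_roundness and min_elongation must lie in [0, 1].")
  }
  structure(p, class = "npq_detection_params")
}

#' Segment candidate inclusions in a DAB intensity map
#'
#' Gaussian-smooths the map (sigma = `smoothing_radius_um`), thresholds at
#' the segmentation intensity, and splits touching clusters by watershed on
#' stain darkness, merging adjacent basins whose separating saddle is
#' shallower than `merging_threshold` intensity units. Object features
#' (area, Crofton perimeter, roundness, elongation, mean DAB intensity) are
#' measured on the unsmoothed map so that sizes are not inflated by the blur.
#'
#' @param dab_intensity_map `H x W` DAB pseudo-intensity matrix (0-255).
#' @param roi An [roi_polygon()]; only objects whose pixels all fall in the
#'   ROI mask are candidates (the mask crops the map).
#' @param params A [detection_params()].
#' @param pixel_size_um Pixel size; taken from the map attribute if absent.
#' @return Tibble of candidate objects, one row each: `object_id`, `area_um2`,
#'   `perimeter_um`, `roundness`, `elongation`, `mean_dab_intensity`,
#'   `centroid_x`, `centroid_y`, plus a `pixels` list-column of linear pixel
#'   indices into the map.
#' @export
segment_candidates <- function(dab_intensity_map, roi = NULL,
                               params = detection_params(),
                               pixel_size_um = NULL) {
  ps <- .pixel_size(dab_intensity_map, pixel_size_um)
  img <- dab_intensity_map
  mask <- if (is.null(roi)) {
    matrix(TRUE, nrow(img), ncol(img))
  } else {
    roi_mask(roi, dim(img))
  }
  sigma_px <- params$smoothing_radius_um / ps
  sm <- if (sigma_px > 0) {
    as.matrix(EBImage::gblur(img, sigma = sigma_px, radius = 2 * ceiling(3 * sigma_px) + 1))
  } else {
    img
  }
  fg <- (sm < params$segmentation_intensity_threshold) & mask
  if (!any(fg)) return(.empty_objects())
  # Watershed on stain darkness of the smoothed map; tolerance is the
  # saddle-depth merge threshold in intensity units.
  dark <- (255 - sm) * fg
  labels <- EBImage::watershed(EBImage::as.Image(dark),
                               tolerance = params$merging_threshold, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    px <- which(labels == id)
    # refine to raw-threshold pixels; keep basin if the raw core is empty
    core <- px[img[px] < params$segmentation_intensity_threshold]
    if (length(core) > 0L) px <- core
    .measure_object(px, img, dim(img), ps)
  })
  out <- bind_rows(rows)
  out$object_id <- seq_len(nrow(out))
  out[, c("object_id", setdiff(names(out), "object_id"))]
}

.empty_objects <- function() {
  tibble(object_id = integer(), area_um2 = numeric(), perimeter_um = numeric(),
         roundness = numeric(), elongation = numeric(),
         mean_dab_intensity = numeric(), centroid_x = numeric(),
         centroid_y = numeric(), pixels = list())
}

# Features of one pixel set (linear indices into an H x W map).
.measure_object <- function(px, img, dm, ps) {
  h <- dm[1]
  rows <- ((px - 1L) %% h) + 1L
  cols <- ((px - 1L) %/% h) + 1L
  a_px <- length(px)
  per_px <- .crofton_perimeter(rows, cols)
  x <- cols - 1; y <- rows - 1
  elong <- .ellipse_axis_ratio(x, y)
  tibble(
    area_um2 = a_px * ps^2,
    perimeter_um = per_px * ps,
    roundness = min(1, 4 * pi * a_px / per_px^2),
    elongation = elong,
    mean_dab_intensity = mean(img[px]),
    centroid_x = mean(x),
    centroid_y = mean(y),
    pixels = list(px)
  )
}

# Cauchy-Crofton perimeter estimate from boundary transitions in four
# directions; unbiased for large disks, unlike the pixel-edge count.
.crofton_perimeter <- function(rows, cols) {
  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  h <- max(rows) - r0 + 2L; w <- max(cols) - c0 + 2L
  m <- matrix(0L, h + 1L, w + 1L)
  m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
  trans <- function(a, b) sum(abs(a - b))
  n0   <- trans(m[, -1], m[, -ncol(m)])                        # horizontal runs
  n90  <- trans(m[-1, ], m[-nrow(m), ])                        # vertical runs
  n45  <- trans(m[-1, -1], m[-nrow(m), -ncol(m)])              # diagonal
  n135 <- trans(m[-1, -ncol(m)], m[-nrow(m), -1])              # anti-diagonal
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# Minor/major axis ratio of the best-fit (second-moment) ellipse.
.ellipse_axis_ratio <- function(x, y) {
  if (length(x) < 2L) return(1)
  # half-pixel variance regularization: a single-row segment is a 1-px-wide
  # bar, not a degenerate line
  cxx <- mean((x - mean(x))^2) + 1 / 12
  cyy <- mean((y - mean(y))^2) + 1 / 12
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  tr <- cxx + cyy
  dt <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
  l1 <- (tr + dt) / 2
  l2 <- (tr - dt) / 2
  if (l1 <= 0) return(1)
  sqrt(max(0, l2) / l1)
}

#' Filter candidate objects by size, shape and intensity
#'
#' Keeps objects with `min_area_um2 <= area <= max_area_um2`,
#' `roundness >= min_roundness`, `elongation >= min_elongation`, and mean
#' DAB intensity at or below the upper positive threshold (darker than the
#' cutoff).
#'
#' @param objects Tibble from [segment_candidates()].
#' @param params A [detection_params()].
#' @return The subset of `objects` passing all filters.
#' @export
filter_objects <- function(objects, params = detection_params()) {
  objects %>%
    filter(.data$area_um2 >= params$min_area_um2,
           .data$area_um2 <= params$max_area_um2,
           .data$roundness >= params$min_roundness,
           .data$elongation >= params$min_elongation,
           .data$mean_dab_intensity <= params$upper_positive_intensity_threshold)
}

#' Object density per square millimetre
#'
#' @param objects Tibble of (filtered) objects.
#' @param roi An [roi_polygon()].
#' @param dim Image dimension `c(H, W)` used to rasterize the ROI.
#' @param pixel_size_um Pixel size in micrometres.
#' @return One-row tibble: `n_objects`, `roi_area_mm2`, `objects_per_mm2`.
#' @export
count_density <- function(objects, roi, dim, pixel_size_um) {
  area <- roi_area_mm2(roi, dim, pixel_size_um)
  if (area <= 0) abort("ROI has zero area.")
  tibble(n_objects = nrow(objects),
         roi_area_mm2 = area,
         objects_per_mm2 = nrow(objects) / area)
}

#' Histogram of objects per unit mean intensity
#'
#' @param objects Tibble with a `mean_dab_intensity` column.
#' @return Integer vector of length 256; element `i` counts objects whose
#'   mean DAB intensity falls in bin `i - 1` (bin `b` covers
#'   `[b, b + 1)`, with 255 included in the last bin). Sums to `nrow(objects)`.
#' @export
intensity_histogram <- function(objects) {
  h <- integer(256)
  if (nrow(objects) > 0L) {
    b <- pmin(floor(objects$mean_dab_intensity), 255)
    tb <- table(b)
    h[as.integer(names(tb)) + 1L] <- as.integer(tb)
  }
  names(h) <- 0:255
  h
}

#' Calibrate the upper positive intensity threshold from training slides
#'
#' Pools the per-slide object-intensity histograms and returns the smallest
#' threshold `t` such that the pooled positive slides' cumulative object
#' fraction at `t` is at least `positive_percentile`% while the pooled
#' negative slides' fraction is at most `negative_percentile`% (the
#' 99th/60th percentile rule from 5 positive and 5 negative training
#' slides). If no threshold satisfies both constraints the threshold
#' maximizing the positive-minus-negative cumulative fraction is returned
#' and flagged `unconstrained`.
#'
#' @param positive_histograms,negative_histograms Lists of length-256
#'   histograms from [intensity_histogram()] (one per training slide).
#' @param positive_percentile,negative_percentile Percentile targets
#'   (defaults 99 and 60).
#' @return One-row tibble: `threshold` (0-255), `positive_capture`,
#'   `negative_capture` (pooled cumulative fractions at the threshold), and
#'   `unconstrained` (logical).
#' @export
calibrate_positive_threshold <- function(positive_histograms,
                                         negative_histograms,
                                         positive_percentile = 99,
                                         negative_percentile = 60) {
  if (length(positive_histograms) == 0L || length(negative_histograms) == 0L) {
    abort("Need at least one positive and one negative training histogram.")
  }
  pool <- function(hs) {
    s <- Reduce(`+`, hs)
    if (length(s) != 256L) abort("Histograms must have 256 bins.")
    if (sum(s) == 0) abort("Pooled training histogram is empty.")
    cumsum(s) / sum(s)
  }
  fp <- pool(positive_histograms)
  fn <- pool(negative_histograms)
  ok <- fp >= positive_percentile / 100 & fn <= negative_percentile / 100
  if (any(ok)) {
    t <- which(ok)[1] - 1L
    unc <- FALSE
  } else {
    t <- which.max(fp - fn) - 1L
    unc <- TRUE
  }
  out <- tibble(threshold = as.integer(t),
                positive_capture = fp[t + 1L],
                negative_capture = fn[t + 1L],
                unconstrained = unc)
  class(out) <- c("npq_calibration", class(out))
  out
}

#' Count inclusions in one image end to end
#'
#' Convenience pipeline: deconvolve the image, segment and filter candidate
#' inclusions in each ROI, and report densities.
#'
#' @param image An [rgb_image()].
#' @param rois A list of [roi_polygon()] (or a single one).
#' @param params A [detection_params()].
#' @param model A [stain_model()].
#' @return Tibble with one row per ROI: `roi_id`, `n_objects`,
#'   `roi_area_mm2`, `objects_per_mm2`.
#' @export
count_inclusions <- function(image, rois, params = detection_params(),
                             model = stain_model()) {
  if (inherits(rois, "npq_roi")) rois <- list(rois)
  if (is.null(names(rois))) names(rois) <- paste0("roi_", seq_along(rois))
  dab <- stain_to_intensity(deconvolve(rgb_to_od(image), model)$dab)
  purrr::imap(rois, function(roi, id) {
    obj <- segment_candidates(dab, roi, params) %>% filter_objects(params)
    count_density(obj, roi, dim(dab), image$pixel_size_um) %>%
      mutate(roi_id = id, .before = 1)
  }) %>% bind_rows()
}
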