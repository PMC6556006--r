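test_that("disjoint planted disks are each recovered with accurate area", {
  sim <- render_ihc_image(
    width_px = 300, height_px = 300, noise_sd = 0,
    objects = tibble::tibble(x = c(60, 150, 240), y = c(60, 150, 240),
                             shape = "disk", area_um2 = 50, dab_od = 0.23),
    seed = 3)
  obj <- segment_candidates(dab_intensity(sim$image))
  expect_equal(nrow(obj), 3)
  expect_true(all(abs(obj$area_um2 - 50) / 50 < 0.1))
  expect_true(all(abs(obj$mean_dab_intensity - 255 * 10^-0.23) < 1))
})

test_that("a blank image yields no candidate objects", {
  blank <- rgb_image(array(255, c(50, 50, 3)))
  obj <- segment_candidates(dab_intensity(blank))
  expect_equal(nrow(obj), 0)
})

test_that("declustering merges shallow saddles and splits deep ones", {
  two <- tibble::tibble(x = c(80, 110), y = c(80, 80), shape = "disk",
                        area_um2 = 120, dab_od = 0.3)
  shallow <- tibble::tibble(from = 1, to = 2, dab_od = 0.3, width_um = 10)
  deep <- tibble::tibble(from = 1, to = 2, dab_od = 0.085, width_um = 10)
  s1 <- render_ihc_image(width_px = 200, height_px = 160, noise_sd = 0,
                         objects = two, bridges = shallow, seed = 1)
  s2 <- render_ihc_image(width_px = 200, height_px = 160, noise_sd = 0,
                         objects = two, bridges = deep, seed = 1)
  expect_equal(nrow(segment_candidates(dab_intensity(s1$image))), 1)
  expect_equal(nrow(segment_candidates(dab_intensity(s2$image))), 2)
})

test_that("segmentation requires a pixel size", {
  m <- matrix(255, 10, 10)
  expect_error(segment_candidates(m), "pixel size")
})

test_that("shape and size filters keep compliant disks and drop violators", {
  objs <- tibble::tibble(
    x = c(50, 130, 220, 60, 200), y = c(50, 50, 60, 200, 220),
    shape = c("disk", "disk", "fiber", "disk", "disk"),
    area_um2 = c(10, 300, 60, 50, 50),
    dab_od = c(0.3, 0.3, 0.3, 0.09, 0.3))  # 0.09 OD ~ intensity 207 (too faint)
  sim <- render_ihc_image(width_px = 500, height_px = 500, noise_sd = 0,
                          objects = objs, seed = 2)
  cand <- segment_candidates(dab_intensity(sim$image))
  kept <- filter_objects(cand)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$area_um2, 48.25, tolerance = 0.1)
  # the fiber candidate itself fails the roundness floor
  fib <- cand[which.max(cand$perimeter_um), ]
  expect_lt(fib$roundness, 0.25)
})

test_that("every filter parameter acts monotonically on the kept count", {
  set.seed(11)
  objs <- tibble::tibble(area_um2 = runif(60, 5, 400),
                         roundness = runif(60), elongation = runif(60),
                         mean_dab_intensity = runif(60, 80, 255))
  n_kept <- function(...) nrow(filter_objects(objs, detection_params(...)))
  expect_true(all(diff(vapply(c(5, 20, 50, 100), function(v)
    n_kept(min_area_um2 = v), 0)) <= 0))
  expect_true(all(diff(vapply(c(100, 225, 350, 400), function(v)
    n_kept(max_area_um2 = v), 0)) >= 0))
  expect_true(all(diff(vapply(c(0, 0.25, 0.5, 0.9), function(v)
    n_kept(min_roundness = v), 0)) <= 0))
  expect_true(all(diff(vapply(c(0, 0.1, 0.5, 0.9), function(v)
    n_kept(min_elongation = v), 0)) <= 0))
  expect_true(all(diff(vapply(c(100, 150, 200, 255), function(v)
    n_kept(upper_positive_intensity_threshold = v), 0)) >= 0))
})

test_that("object density is count over ROI area and rejects zero area", {
  roi <- roi_rect(0, 0, 40, 40)           # 400 um^2 at 0.5 um/px... scaled below
  objs <- tibble::tibble(area_um2 = rep(50, 5))
  res <- count_density(objs, roi, c(40, 40), pixel_size_um = 0.5)
  expect_equal(res$objects_per_mm2, 5 / (1600 * 0.25 / 1e6))
  expect_equal(count_density(objs[0, ], roi, c(40, 40), 0.5)$objects_per_mm2, 0)
})

test_that("density is invariant to tiling the ROI into halves", {
  sim <- render_ihc_image(
    width_px = 200, height_px = 100, noise_sd = 0,
    objects = tibble::tibble(x = c(30, 60, 140, 170), y = c(30, 70, 40, 70),
                             shape = "disk", area_um2 = 50, dab_od = 0.3),
    seed = 5)
  dab <- dab_intensity(sim$image)
  whole <- roi_rect(0, 0, 200, 100)
  left <- roi_rect(0, 0, 100, 100)
  right <- roi_rect(100, 0, 200, 100)
  n <- function(roi) nrow(filter_objects(segment_candidates(dab, roi)))
  a <- function(roi) roi_area_mm2(roi, dim(dab), 0.5)
  d_whole <- n(whole) / a(whole)
  d_tiled <- (n(left) + n(right)) / (a(left) + a(right))
  expect_equal(d_whole, d_tiled)
})

test_that("roundness approaches 1 for large disks; elongation tracks ellipse axes", {
  mk_disk <- function(area) {
    sim <- render_ihc_image(width_px = 600, height_px = 600, noise_sd = 0,
      objects = tibble::tibble(x = 300, y = 300, shape = "disk",
                               area_um2 = area, dab_od = 0.4), seed = 1)
    segment_candidates(dab_intensity(sim$image),
                       params = detection_params(max_area_um2 = 1e9))
  }
  small <- mk_disk(30); big <- mk_disk(5000)
  expect_gt(big$roundness, 0.97)
  expect_gte(big$roundness, small$roundness - 0.05)
  sim_e <- render_ihc_image(width_px = 400, height_px = 400, noise_sd = 0,
    objects = tibble::tibble(x = 200, y = 200, shape = "ellipse",
                             area_um2 = 2000, dab_od = 0.4, axis_ratio = 1 / 3,
                             angle = 0.5), seed = 1)
  ell <- segment_candidates(dab_intensity(sim_e$image),
                            params = detection_params(max_area_um2 = 1e9))
  expect_equal(ell$elongation, 1 / 3, tolerance = 0.1)
})

test_that("intensity histogram conserves object counts", {
  objs <- tibble::tibble(mean_dab_intensity = c(100.2, 100.9, 17, 254.5))
  h <- intensity_histogram(objs)
  expect_length(h, 256)
  expect_equal(unname(h[101]), 2)   # bin 100
  expect_equal(unname(h[18]), 1)
  expect_equal(sum(h), 4)
  expect_equal(sum(intensity_histogram(objs[0, ])), 0)
})

test_that("threshold calibration separates positive from negative training sets", {
  set.seed(21)
  pos <- lapply(1:5, function(i) intensity_histogram(
    tibble::tibble(mean_dab_intensity = runif(40, 90, 150))))
  neg <- lapply(1:5, function(i) intensity_histogram(
    tibble::tibble(mean_dab_intensity = runif(15, 240, 254))))
  cal <- calibrate_positive_threshold(pos, neg)
  expect_false(cal$unconstrained)
  expect_gte(cal$threshold, 90)
  expect_lte(cal$threshold, 239)
  expect_gte(cal$positive_capture, 0.99)
  expect_lte(cal$negative_capture, 0.60)
})

test_that("inseparable training sets are flagged unconstrained", {
  same <- intensity_histogram(tibble::tibble(mean_dab_intensity = rep(100, 10)))
  cal <- calibrate_positive_threshold(list(same), list(same))
  expect_true(cal$unconstrained)
  expect_error(calibrate_positive_threshold(list(), list(same)), "at least one")
})
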