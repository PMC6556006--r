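test_that("optical-density transform matches Beer-Lambert with clamping", {
  expect_equal(as.numeric(rgb_to_od(255)), 0)
  expect_equal(as.numeric(rgb_to_od(25.5)), 1)
  expect_equal(as.numeric(rgb_to_od(0)), log10(255))  # clamp at saturation
  # monotone decreasing in intensity
  i <- seq(0, 255, by = 0.5)
  expect_true(all(diff(as.numeric(rgb_to_od(i))) <= 0))
})

test_that("stain_to_intensity inverts the OD transform", {
  expect_equal(as.numeric(stain_to_intensity(0)), 255)
  expect_equal(as.numeric(stain_to_intensity(1)), 25.5)
  i <- seq(1, 255, by = 0.25)
  back <- as.numeric(stain_to_intensity(rgb_to_od(i)))
  expect_lt(max(abs(back - i)), 0.5)
  expect_error(stain_to_intensity(-0.1), "non-negative")
})

test_that("stain model vectors are unit length and invertible", {
  m <- stain_model()
  expect_equal(unname(rowSums(m$vectors^2)), rep(1, 3))
  expect_equal(unname(m$unmix %*% t(m$vectors)), diag(3), tolerance = 1e-12)
  expect_error(stain_model(hematoxylin = c(1, 0, 0), dab = c(1, 0, 0)),
               "Singular")
})

test_that("deconvolution recovers single stains and mixtures", {
  m <- stain_model()
  mk <- function(hem, dab) synth_rgb(matrix(hem, 2, 2), matrix(dab, 2, 2), m)
  pure_hem <- deconvolve(rgb_to_od(mk(1, 0)), m)
  expect_equal(pure_hem$hematoxylin[1, 1], 1, tolerance = 1e-6)
  expect_equal(pure_hem$dab[1, 1], 0, tolerance = 1e-6)
  expect_equal(pure_hem$residual[1, 1], 0, tolerance = 1e-6)
  blank <- deconvolve(rgb_to_od(rgb_image(array(255, c(2, 2, 3)))), m)
  expect_true(all(vapply(blank, max, 0) == 0))
  mix <- deconvolve(rgb_to_od(mk(0.5, 0.3)), m)
  expect_equal(mix$hematoxylin[1, 1], 0.5, tolerance = 1e-6)
  expect_equal(mix$dab[1, 1], 0.3, tolerance = 1e-6)
})

test_that("deconvolution round-trips arbitrary planted OD maps", {
  set.seed(42)
  for (rep in 1:3) {
    od_h <- matrix(runif(400, 0, 1.2), 20, 20)
    od_d <- matrix(runif(400, 0, 1.2), 20, 20)
    maps <- deconvolve(rgb_to_od(synth_rgb(od_h, od_d)), stain_model())
    expect_lt(max(abs(maps$hematoxylin - od_h)), 1e-4)
    expect_lt(max(abs(maps$dab - od_d)), 1e-4)
    expect_lt(max(abs(maps$residual)), 1e-4)
  }
})

test_that("deconvolution with an orthonormal basis is per-channel OD", {
  m <- stain_model(hematoxylin = c(1, 0, 0), dab = c(0, 1, 0),
                   residual = c(0, 0, 1))
  img <- rgb_image(array(runif(27, 10, 255), c(3, 3, 3)))
  od <- rgb_to_od(img)
  maps <- deconvolve(od, m)
  expect_equal(maps$hematoxylin, od[, , 1], ignore_attr = TRUE)
  expect_equal(maps$dab, od[, , 2], ignore_attr = TRUE)
  expect_equal(maps$residual, od[, , 3], ignore_attr = TRUE)
})

test_that("area analysis handles uniform, blank, and half-positive ROIs", {
  roi <- roi_rect(0, 0, 20, 20)
  uniform <- matrix(stain_to_intensity(0.5), 20, 20)  # OD 0.5 everywhere
  res <- area_analysis(uniform, roi, pixel_size_um = 0.5)
  expect_equal(res$percent_positive, 100)
  expect_equal(res$od_weighted_metric, 50, tolerance = 1e-6)
  blank <- matrix(255, 20, 20)
  res0 <- area_analysis(blank, roi, pixel_size_um = 0.5)
  expect_equal(res0$percent_positive, 0)
  expect_equal(res0$od_weighted_metric, 0)
  half <- matrix(255, 20, 20); half[, 1:10] <- 25.5  # OD 1.0 on half
  res5 <- area_analysis(half, roi, pixel_size_um = 0.5)
  expect_equal(res5$percent_positive, 50)
  expect_equal(res5$avg_positive_od, 1)
  expect_equal(res5$od_weighted_metric, 50)
})

test_that("burden metric is invariant to ROI translation and pixel permutation", {
  set.seed(7)
  img <- matrix(runif(3600, 100, 255), 60, 60)
  block <- img[11:30, 11:30]
  shifted <- matrix(255, 60, 60); shifted[31:50, 26:45] <- block
  r1 <- area_analysis(img, roi_rect(10, 10, 30, 30), pixel_size_um = 0.5)
  r2 <- area_analysis(shifted, roi_rect(25, 30, 45, 50), pixel_size_um = 0.5)
  expect_equal(r1$od_weighted_metric, r2$od_weighted_metric)
  permuted <- matrix(255, 60, 60)
  permuted[11:30, 11:30] <- matrix(sample(as.vector(block)), 20, 20)
  r3 <- area_analysis(permuted, roi_rect(10, 10, 30, 30), pixel_size_um = 0.5)
  expect_equal(r1$od_weighted_metric, r3$od_weighted_metric)
})

test_that("lowering the positive threshold never increases percent positive", {
  set.seed(8)
  img <- matrix(runif(900, 0, 255), 30, 30)
  roi <- roi_rect(0, 0, 30, 30)
  pct <- vapply(seq(255, 5, by = -25), function(th) {
    area_analysis(img, roi, threshold = th, pixel_size_um = 0.5)$percent_positive
  }, 0)
  expect_true(all(diff(pct) <= 0))
})

test_that("area analysis rejects an empty ROI", {
  img <- matrix(255, 10, 10)
  tiny <- roi_polygon(cbind(c(2.1, 2.4, 2.4), c(2.1, 2.1, 2.4)))  # no center
  expect_error(area_analysis(img, tiny, pixel_size_um = 0.5), "no pixels")
})

test_that("limbic-predominant subtype rule uses a strict 1.5 ratio", {
  expect_equal(tau_subtype_ratio(3, 1), "limbic-predominant")
  expect_equal(tau_subtype_ratio(1, 1), "not limbic-predominant")
  expect_equal(tau_subtype_ratio(1.5, 1), "not limbic-predominant")  # boundary
  expect_error(tau_subtype_ratio(1, 0), "undefined")
})
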