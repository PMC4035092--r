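gauss_field <- function(nr, nc, peaks, background = 10) {
  img <- matrix(background, nr, nc)
  for (p in peaks)
    img <- img + p$amp * exp(-(outer((seq_len(nr) - p$r)^2,
                                     (seq_len(nc) - p$c)^2, "+")) /
                               (2 * p$sigma^2))
  img
}

test_that("flat fields yield no foci; an isolated peak yields exactly one", {
  flat <- channel_image(matrix(7, 20, 20), 1)
  expect_identical(nrow(detect_foci(flat, NULL, detection_params(0.5))$coordinates), 0L)

  img <- gauss_field(41, 41, list(list(r = 21, c = 19, amp = 100, sigma = 3)))
  fs <- detect_foci(channel_image(img, 1), NULL, detection_params(50))
  expect_identical(nrow(fs$coordinates), 1L)
  expect_lte(max(abs(fs$coordinates - c(21, 19))), 1)
})

test_that("tolerance above the dynamic range warns and returns nothing", {
  img <- gauss_field(21, 21, list(list(r = 11, c = 11, amp = 20, sigma = 2)))
  expect_warning(fs <- detect_foci(channel_image(img, 1), NULL,
                                   detection_params(500)), "dynamic range")
  expect_identical(nrow(fs$coordinates), 0L)
})

test_that("raising the tolerance never increases the focus count", {
  set.seed(31)
  img <- channel_image(matrix(runif(50 * 50, 0, 100), 50, 50), 1)
  counts <- vapply(c(1, 5, 10, 20, 40, 80),
                   function(tol) nrow(detect_foci(img, NULL,
                     detection_params(tol))$coordinates), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detections are translation-equivariant and offset-invariant", {
  set.seed(32)
  base <- gauss_field(40, 40, list(list(r = 12, c = 15, amp = 80, sigma = 2),
                                   list(r = 28, c = 30, amp = 60, sigma = 2))) +
    matrix(runif(1600, 0, 3), 40, 40)
  big <- matrix(0, 60, 60); big[1:40, 1:40] <- base
  shifted <- matrix(0, 60, 60); shifted[11:50, 6:45] <- base
  p <- detection_params(30)
  f1 <- detect_foci(channel_image(big, 1), rect_roi(c(1, 40), c(1, 40)), p)
  f2 <- detect_foci(channel_image(shifted, 1), rect_roi(c(11, 50), c(6, 45)), p)
  o1 <- order(f1$coordinates[, 1]); o2 <- order(f2$coordinates[, 1])
  expect_equal(f2$coordinates[o2, , drop = FALSE],
               sweep(f1$coordinates[o1, , drop = FALSE], 2, c(-10, -5)),
               ignore_attr = TRUE)
  # adding a constant changes nothing (prominence is offset-free)
  f3 <- detect_foci(channel_image(big + 55, 1), rect_roi(c(1, 40), c(1, 40)), p)
  expect_identical(f3$coordinates, f1$coordinates)
  expect_equal(f3$scores, f1$scores)
})

test_that("prominences match the brute-force highest-saddle oracle", {
  set.seed(33)
  for (rep in 1:12) {
    img <- if (rep <= 6) matrix(runif(15 * 15, 0, 100), 15, 15)
           else matrix(sample(0:12, 15 * 15, TRUE), 15, 15)  # heavy plateaus
    got <- wmquant:::cpp_find_maxima(img, matrix(TRUE, 15, 15))
    want <- bf_prominences(img)
    expect_identical(nrow(got), nrow(want))
    expect_equal(sort(got$prominence), sort(want$prominence), tolerance = 1e-12)
    expect_equal(sort(got$value), sort(want$height), tolerance = 1e-12)
  }
})

test_that("plateau maxima collapse to a single centroid detection", {
  img <- matrix(0, 21, 21)
  img[9:13, 9:13] <- 50                  # 5x5 flat-top focus
  fs <- detect_foci(channel_image(img, 1), NULL, detection_params(10))
  expect_identical(nrow(fs$coordinates), 1L)
  expect_identical(as.integer(fs$coordinates[1, ]), c(11L, 11L))
})

test_that("counting and area are restricted to the ROI", {
  img <- gauss_field(40, 40, list(list(r = 10, c = 10, amp = 80, sigma = 2),
                                  list(r = 30, c = 30, amp = 80, sigma = 2)))
  ci <- channel_image(img, 1)
  roi <- rect_roi(c(1, 20), c(1, 20))
  fs <- detect_foci(ci, roi, detection_params(40))
  expect_identical(nrow(fs$coordinates), 1L)
  expect_equal(fs$roi_area_mm2, 400 / 1e6)
  expect_equal(debris_density(fs), 1 / (400 / 1e6))
})

test_that("density arithmetic is exact and pixel-size independent", {
  img <- gauss_field(40, 40, list(list(r = 20, c = 20, amp = 80, sigma = 2)))
  fs <- detect_foci(channel_image(img, 1), NULL, detection_params(40))
  fs$roi_area_mm2 <- 0.01
  expect_equal(30 / 0.01, 3000)          # the quotient the readout reports
  expect_equal(debris_density(fs), nrow(fs$coordinates) / fs$roi_area_mm2)

  # same physical scene at 2x resolution: density within 5%
  f1 <- gen_foci_image(25, shape = c(128L, 128L), sigma_px = 2,
                       pixel_size_um = 0.64, seed = 40)
  fs1 <- detect_foci(f1$image, NULL, detection_params(20))
  f2 <- gen_foci_image(25, shape = c(256L, 256L), sigma_px = 4,
                       min_separation_px = 12, pixel_size_um = 0.32, seed = 40)
  fs2 <- detect_foci(f2$image, NULL, detection_params(20))
  expect_lt(abs(debris_density(fs1) - debris_density(fs2)) /
              debris_density(fs2), 0.05)
})

test_that("tolerance calibration maximizes F1 with ties toward larger values", {
  # clean high-contrast foci: a wide plateau of perfect F1; the largest
  # tolerance on the plateau must be returned
  cal <- lapply(1:4, function(s) {
    f <- gen_foci_image(30, shape = c(128L, 128L), amplitude_range = c(100, 100),
                        noise_sd = 2, seed = s)
    list(image = f$image, centers = f$truth$centers)
  })
  res <- calibrate_tolerance(cal, grid = seq(10, 80, by = 10))
  expect_equal(res$mean_f1, 1)
  plateau <- res$f1_by_tolerance$tolerance[res$f1_by_tolerance$mean_f1 == 1]
  expect_identical(res$noise_tolerance, max(plateau))

  # degenerate single-point grid is returned with its (possibly poor) F1
  res1 <- calibrate_tolerance(cal, grid = 1)
  expect_identical(res1$noise_tolerance, 1)
  expect_true(res1$mean_f1 <= 1)

  expect_error(calibrate_tolerance(cal, numeric(0)), "empty")
  expect_error(calibrate_tolerance(cal[1:2], 10), "at least 3")
  empty <- lapply(1:3, function(s) list(
    image = channel_image(matrix(1, 8, 8), 1), centers = matrix(0, 0, 2)))
  expect_error(calibrate_tolerance(empty, 10), "zero|no true", ignore.case = TRUE)
})
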