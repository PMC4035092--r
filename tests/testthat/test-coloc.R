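# annulus + optional punctum phantom used across colocalization tests
phantom <- function(nr = 61, nc = 61, ctr = c(31, 31), r0 = 6, amp = 100,
                    punctum = NULL, fill = 0.75) {
  d <- sqrt(outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, "+"))
  red <- amp * exp(-(d - r0)^2 / (2 * 1.2^2))
  red <- pmax(red, fill * amp * (d < r0))
  green <- matrix(0, nr, nc)
  if (!is.null(punctum)) {
    d2 <- outer((seq_len(nr) - punctum[1])^2, (seq_len(nc) - punctum[2])^2, "+")
    green <- amp * exp(-d2 / (2 * 1.2^2))
  }
  list(red = channel_image(red + 1, 1), green = channel_image(green + 1, 1))
}

test_that("profiles sample both channels along perpendicular unit-step lines", {
  # horizontal line through a one-pixel-wide vertical green stripe
  green <- matrix(0, 21, 21); green[, 11] <- 50
  red <- matrix(seq_len(21 * 21), 21, 21)
  pp <- extract_profiles(channel_image(red, 1), channel_image(green, 1),
                         c(11, 11), length_px = 15, angle_deg = 0)
  g1 <- pp$green_profiles[[1]]
  expect_identical(sum(g1 == 50), 1L)               # single stripe crossing
  expect_identical(which(g1 == 50), (15L + 1L) %/% 2L)
  # perpendicular line runs along the stripe: all samples on it
  expect_true(all(pp$green_profiles[[2]] == 50))

  # reversing the angle reverses the samples
  pa <- extract_profiles(channel_image(red, 1), channel_image(green, 1),
                         c(11, 11), 15, angle_deg = 0)
  pb <- extract_profiles(channel_image(red, 1), channel_image(green, 1),
                         c(11, 11), 15, angle_deg = 180)
  expect_identical(pa$red_profiles[[1]], rev(pb$red_profiles[[1]]))
  expect_error(extract_profiles(channel_image(red, 1), channel_image(green, 1),
                                c(50, 50), 15), "outside")
})

test_that("ring phantom gives a bimodal red profile and a central green peak", {
  ph <- phantom(punctum = c(31, 31))
  pp <- extract_profiles(ph$red, ph$green, c(31, 31), length_px = 31)
  red <- pp$red_profiles[[1]]
  pk <- wmquant:::peaks_1d(red)
  expect_gte(nrow(pk[pk$prominence > 5, ]), 2L)      # two rim crossings
  gpk <- wmquant:::peaks_1d(pp$green_profiles[[1]])
  expect_identical(gpk$index[which.max(gpk$prominence)], 16L)  # center sample
})

test_that("axon calls follow the green-peak-within-red-support rule", {
  # null green channel -> absent
  ph0 <- phantom()
  pp0 <- extract_profiles(ph0$red, ph0$green, c(31, 31), 31)
  expect_identical(classify_axon(pp0, 10)$call, "axon_absent")

  # central punctum -> present on both lines
  ph1 <- phantom(punctum = c(31, 31))
  pp1 <- extract_profiles(ph1$red, ph1$green, c(31, 31), 31)
  call1 <- classify_axon(pp1, 10)
  expect_identical(call1$call, "axon_present")
  expect_identical(call1$supporting_line, "both")

  # lateral punctum (half ring radius off-center) -> present
  ph2 <- phantom(punctum = c(31, 34))
  pp2 <- extract_profiles(ph2$red, ph2$green, c(31, 31), 31)
  expect_identical(classify_axon(pp2, 10)$call, "axon_present")

  # punctum outside the ring support -> absent
  ph3 <- phantom(punctum = c(31, 52))
  pp3 <- extract_profiles(ph3$red, ph3$green, c(31, 31), 31)
  expect_identical(classify_axon(pp3, 10)$call, "axon_absent")

  # flat red profile -> absent with the flag set
  flat <- extract_profiles(channel_image(matrix(5, 41, 41), 1),
                           channel_image(matrix(5, 41, 41), 1), c(21, 21), 21)
  cf <- classify_axon(flat, 5)
  expect_identical(cf$call, "axon_absent")
  expect_true(cf$flat_red)
})

test_that("the call is rotation-robust for the ring + central punctum", {
  ph <- phantom(punctum = c(31, 31))
  for (a in seq(0, 165, by = 15)) {
    pp <- extract_profiles(ph$red, ph$green, c(31, 31), 31, angle_deg = a)
    expect_identical(classify_axon(pp, 10)$call, "axon_present")
  }
})

test_that("raising the green prominence never creates an axon call", {
  cc <- gen_coloc_image(30, 0.5, seed = 9)
  centers <- select_debris(cc$red, 30, detection_params(50), seed = 1)
  for (i in seq_len(nrow(centers))) {
    pp <- extract_profiles(cc$red, cc$green, centers[i, ], 41)
    calls <- vapply(c(5, 20, 60, 120),
                    function(pr) classify_axon(pp, pr)$call == "axon_present",
                    TRUE)
    expect_true(all(diff(calls) <= 0))     # present can only turn absent
  }
})

test_that("debris selection is seeded, clamped, and blind to the green channel", {
  cc <- gen_coloc_image(30, 0.5, seed = 4)
  s1 <- select_debris(cc$red, 15, detection_params(50), seed = 7)
  s2 <- select_debris(cc$red, 15, detection_params(50), seed = 7)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 15L)
  expect_warning(all_of <- select_debris(cc$red, 500, detection_params(50)),
                 "returning all")
  expect_lte(nrow(all_of), 35L)

  # poisoned green channel: selection and calls derive from red + profiles only
  poison <- channel_image(matrix(runif(prod(dim(cc$green$pixels)), 0, 255),
                                 nrow(cc$green$pixels)), cc$green$pixel_size_um)
  r1 <- coloc_field(cc$red, cc$green, 15, detection_params(50), 41,
                    peak_prominence = 20, seed = 3)
  r2 <- coloc_field(cc$red, poison, 15, detection_params(50), 41,
                    peak_prominence = 20, seed = 3)
  expect_identical(r1$centers, r2$centers)
})

test_that("axon fraction arithmetic and ground-truth recovery", {
  calls <- c(replicate(10, structure(list(call = "axon_present"), class = "AxonCall"),
                       simplify = FALSE),
             replicate(10, structure(list(call = "axon_absent"), class = "AxonCall"),
                       simplify = FALSE))
  expect_equal(axon_fraction(calls), 50)
  expect_equal(axon_fraction(calls[11:20]), 0)
  expect_error(axon_fraction(list()), "no calls")

  cc <- gen_coloc_image(80, 0.5, seed = 21)
  res <- coloc_field(cc$red, cc$green, 80, detection_params(50), 41,
                     peak_prominence = 20, seed = 1)
  realized <- 100 * cc$truth$axon_present_fraction
  expect_lt(abs(res$percent_axon_present - realized), 10)
})
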