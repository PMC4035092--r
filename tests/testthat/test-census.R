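one_mouse_table <- function(n_vac, n_whorl, n_other, mouse = "m1") {
  data.frame(mouse_id = mouse,
             lesion_type = rep(c("vacuole", "myelin_whorl", "other"),
                               c(n_vac, n_whorl, n_other)),
             location = "intramyelinic", layer = "innermost",
             axon_status = "intact", microglia_contact = "no",
             area_um2 = NA_real_)
}

test_that("census percentages are exact per mouse and sum to 100", {
  tab <- one_mouse_table(768, 147, 85)
  cf <- census_fractions(tab, "lesion_type")
  got <- cf$summary$mean_pct[match(c("vacuole", "myelin_whorl", "other"),
                                   cf$summary$category)]
  expect_equal(got, c(76.8, 14.7, 8.5))
  expect_equal(sum(cf$per_mouse), 100)

  # identical mice: SEM 0, single-category axis gives 100%
  tab2 <- rbind(one_mouse_table(10, 0, 0, "m1"), one_mouse_table(10, 0, 0, "m2"))
  cf2 <- census_fractions(tab2, "lesion_type")
  expect_equal(cf2$summary$mean_pct, 100)
  expect_equal(cf2$summary$sem_pct, 0)
  expect_error(census_fractions(tab[0, ], "lesion_type"), "empty")

  # per-mouse rows always sum to 100 before averaging
  mix <- lesion_mixture(n_mice = 6L)
  t3 <- gen_lesion_table(mix, seed = 5)
  for (axis in c("lesion_type", "location", "axon_status"))
    expect_equal(unname(rowSums(census_fractions(t3, axis)$per_mouse)),
                 rep(100, 6))
})

test_that("mixture recovery: vacuole share within binomial error", {
  mix <- lesion_mixture(lesion_type_probs = c(vacuole = 0.75,
                                              myelin_whorl = 0.17, other = 0.08),
                        n_mice = 4L, n_lesions_per_mouse = 200L)
  tab <- gen_lesion_table(mix, seed = 11)
  cf <- census_fractions(tab, "lesion_type")
  expect_lt(abs(cf$summary$mean_pct[cf$summary$category == "vacuole"] - 75), 4)
})

test_that("equivalent diameter is exact and monotone", {
  expect_equal(equivalent_diameter(pi / 4), 1)
  expect_equal(equivalent_diameter(pi), 2)
  expect_error(equivalent_diameter(0), "positive")
  a <- sort(runif(20, 0.1, 5))
  expect_true(all(diff(equivalent_diameter(a)) > 0))
  # digitized disk: d_eq approaches the true diameter as pixels refine
  d_eq <- vapply(c(1, 0.25), function(ps) {
    n <- round(40 / ps)
    ctr <- (n + 1) / 2
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
    equivalent_diameter(sum(d2 <= (10 / ps)^2) * ps^2)
  }, 0)
  expect_lt(abs(d_eq[2] - 20), abs(d_eq[1] - 20) + 1e-9)
  expect_lt(abs(d_eq[2] - 20) / 20, 0.01)
})

test_that("size distribution: median, sub-micrometre share, histogram", {
  tab <- data.frame(mouse_id = "m1", lesion_type = "vacuole",
                    location = "intramyelinic", layer = "innermost",
                    axon_status = "intact", microglia_contact = "no",
                    area_um2 = pi * 0.8^2 / 4)
  sz <- size_distribution(tab)
  expect_equal(sz$median_um, 0.8)
  expect_equal(sz$fraction_below_1um, 1)
  expect_identical(sum(sz$histogram$count), 1L)

  # sphere-section areas: observed median d_eq = sqrt(3)/2 of the true D
  d <- sample_sphere_sections(1.0, 1e5, seed = 2)
  tab2 <- data.frame(mouse_id = rep(c("m1", "m2"), length.out = 1e5),
                     lesion_type = "vacuole", location = "intramyelinic",
                     layer = "innermost", axon_status = "intact",
                     microglia_contact = "no", area_um2 = pi * d^2 / 4)
  sz2 <- size_distribution(tab2)
  expect_lt(abs(sz2$median_um - sqrt(3) / 2), 0.01)
  expect_error(size_distribution(one_mouse_table(0, 5, 0)), "no vacuole")
})

test_that("eccentric-sectioning correction inverts the sphere-profile bias", {
  expect_equal(correct_section_median(0.7, 1.0)$estimated_true_diameter_um, 0.7)
  # observed sqrt(3)/2 with the default factor recovers D = 1
  res <- correct_section_median(sqrt(3) / 2)
  expect_equal(res$estimated_true_diameter_um, 1.0, tolerance = 1e-12)
  expect_equal(res$correction_factor, 2 / sqrt(3))
  # the 0.83 um observed median maps to 0.958 um under the sphere model
  expect_equal(correct_section_median(0.83)$estimated_true_diameter_um,
               0.83 * 2 / sqrt(3), tolerance = 1e-12)
  expect_error(correct_section_median(-1), "positive")
  expect_error(correct_section_median(1, 0), "positive")
})

test_that("frame density arithmetic and mouse-first aggregation", {
  fr <- data.frame(mouse_id = "m1", count = 4, frame_area_um2 = 400)
  fd <- frame_density(fr)
  expect_equal(fd$mean, 10)                  # 4 per 400 um^2 = 10 per 1000
  expect_true(is.na(fd$sem))
  expect_equal(frame_density(data.frame(mouse_id = "m1", count = 0))$mean, 0)
  fr2 <- data.frame(mouse_id = rep(c("m1", "m2"), each = 2),
                    count = c(2, 4, 6, 8), frame_area_um2 = 400)
  fd2 <- frame_density(fr2)
  expect_equal(unname(fd2$per_mouse), c(7.5, 17.5))
  expect_equal(fd2$mean, 12.5)
  expect_error(frame_density(fr[0, ]), "no counting frames")
})

test_that("tiling with two forbidden edges counts every point exactly once", {
  set.seed(61)
  side <- sqrt(400)
  pts <- cbind(runif(2000, 0, 5 * side), runif(2000, 0, 4 * side))
  total <- 0L
  for (ix in 0:4) for (iy in 0:3)
    total <- total + frame_count(pts, ix * side, iy * side, 400)
  expect_identical(total, 2000L)
  # a point exactly on a shared border belongs to exactly one frame
  p_edge <- cbind(side, side / 2)
  owners <- sum(vapply(0:4, function(ix)
    frame_count(p_edge, ix * side, 0, 400), 0L))
  expect_identical(owners, 1L)
})

test_that("microglia-contact percentages aggregate per mouse", {
  tab <- data.frame(mouse_id = "m1",
                    microglia_contact = rep(c("yes", "no"), c(2, 13)))
  cf <- contact_fraction(tab)
  expect_equal(round(cf$mean, 1), 13.3)
  tab2 <- data.frame(mouse_id = rep(c("m1", "m2"), each = 4),
                     microglia_contact = c(rep("yes", 4), rep("no", 4)))
  cf2 <- contact_fraction(tab2)
  expect_equal(unname(cf2$per_mouse), c(100, 0))
  expect_equal(cf2$mean, 50)
  expect_error(contact_fraction(data.frame(mouse_id = "m", microglia_contact = "n/a")),
               "no records")

  mix <- lesion_mixture(contact_prob = 0.06, n_mice = 4L,
                        n_lesions_per_mouse = 300L)
  tab3 <- gen_lesion_table(mix, seed = 13)
  expect_lt(abs(contact_fraction(tab3)$mean - 6), 3)
})
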