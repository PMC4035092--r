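## Synthetic micrograph and annotation-table generators.
##
## Every generator returns the ground truth it actually realized, and is
## deterministic given (parameters, seed). Defaults emulate the acquisition
## conditions the pipelines were designed for (wide-field x20 fields for
## debris and nuclei, x60 confocal fields for colocalization, EM annotation
## tables of ~200 lesions per mouse over 4 mice).

# place n points with minimum pairwise distance by dart throwing
place_points <- function(n, shape, min_dist, margin, max_tries = 20000L) {
  pts <- matrix(NA_real_, n, 2L)
  k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %d points at separation %.3g in a %dx%d field",
                   n, min_dist, shape[1L], shape[2L]))
    p <- c(runif(1, 1 + margin, shape[1L] - margin),
           runif(1, 1 + margin, shape[2L] - margin))
    if (k == 0L ||
        min((pts[seq_len(k), 1L] - p[1L])^2 +
            (pts[seq_len(k), 2L] - p[2L])^2) >= min_dist^2) {
      k <- k + 1L
      pts[k, ] <- p
    }
  }
  pts
}

# add a Gaussian bump of given amplitude/sigma at (r0, c0), in place
add_gaussian <- function(img, r0, c0, amplitude, sigma) {
  ext <- ceiling(4 * sigma)
  rr <- max(1L, floor(r0 - ext)):min(nrow(img), ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(ncol(img), ceiling(c0 + ext))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

# smooth low-order polynomial background with a given peak-to-trough amplitude
poly_background <- function(shape, amplitude, baseline) {
  r <- seq(-1, 1, length.out = shape[1L])
  c <- seq(-1, 1, length.out = shape[2L])
  co <- runif(6, -1, 1)
  b <- co[1] + co[2] * outer(r, rep(1, shape[2L])) +
    co[3] * outer(rep(1, shape[1L]), c) +
    co[4] * outer(r^2, rep(1, shape[2L])) +
    co[5] * outer(rep(1, shape[1L]), c^2) +
    co[6] * outer(r, c)
  rng <- diff(range(b))
  if (rng > 0) b <- (b - min(b)) / rng * amplitude
  b + baseline
}

#' Simulate a wide-field debris image with known foci
#'
#' Emulates an MBP-immunostained white-matter field: a smooth non-uniform
#' background (random quadratic polynomial whose amplitude is comparable to
#' the focus amplitudes, so plain thresholding fails), isotropic Gaussian
#' hyperintense foci with a minimum pairwise separation, and additive
#' Gaussian noise.
#'
#' @param n_foci number of foci to place.
#' @param shape field size in pixels, default `c(256, 256)`.
#' @param amplitude_range uniform range of focus amplitudes above background.
#' @param sigma_px Gaussian radius of a focus (default 2 px).
#' @param noise_sd additive noise SD (default 2).
#' @param background_amplitude peak-to-trough background variation
#'   (default 60, same order as the foci).
#' @param baseline background offset (default 40).
#' @param min_separation_px minimum focus spacing (default `6 * sigma_px`).
#' @param pixel_size_um physical scale (default 0.32, x20 wide-field).
#' @param seed RNG seed.
#' @return `list(image = ChannelImage, truth = FociGroundTruth)`; the truth
#'   holds `n_foci`, `centers`, `amplitudes`, `sigma_px`, `noise_sd` as
#'   realized.
#' @export
gen_foci_image <- function(n_foci, shape = c(256L, 256L),
                           amplitude_range = c(40, 80), sigma_px = 2,
                           noise_sd = 2, background_amplitude = 60,
                           baseline = 40,
                           min_separation_px = 6 * sigma_px,
                           pixel_size_um = 0.32, seed = 1L) {
  n_foci <- as.integer(n_foci)
  set.seed(seed)
  img <- poly_background(shape, background_amplitude, baseline)
  centers <- if (n_foci > 0L)
    place_points(n_foci, shape, min_separation_px, margin = ceiling(3 * sigma_px))
  else matrix(0, 0L, 2L)
  amplitudes <- runif(n_foci, amplitude_range[1L], amplitude_range[2L])
  for (i in seq_len(n_foci))
    img <- add_gaussian(img, centers[i, 1L], centers[i, 2L],
                        amplitudes[i], sigma_px)
  if (noise_sd > 0)
    img <- img + matrix(rnorm(prod(shape), 0, noise_sd), shape[1L], shape[2L])
  img[img < 0] <- 0
  truth <- structure(list(n_foci = n_foci, centers = centers,
                          amplitudes = amplitudes, sigma_px = sigma_px,
                          background = "quadratic polynomial",
                          background_amplitude = background_amplitude,
                          noise_sd = noise_sd), class = "FociGroundTruth")
  list(image = channel_image(img, pixel_size_um, "SMI94-synthetic"),
       truth = truth)
}

# stamp a filled disk of the given value (additively replaces via pmax)
stamp_disk <- function(img, r0, c0, radius, value) {
  rr <- max(1L, floor(r0 - radius)):min(nrow(img), ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- pmax(img[rr, cc], value * (d2 <= radius^2))
  img
}

#' Simulate a two-channel DAPI/Olig2 field with known positive fraction
#'
#' Nuclei are disks of fixed radius; a configurable fraction of nuclei is
#' placed touching an existing nucleus (center distance `1.8 * radius`,
#' i.e. overlapping by up to 20% of the radius — close enough to merge under
#' plain labelling, far enough that a distance-transform watershed separates
#' them). Olig2-positive nuclei carry a mean marker intensity `contrast`
#' times the background; positivity flags are drawn per nucleus.
#'
#' @param n_nuclei number of nuclei.
#' @param shape field size, default `c(400, 400)`.
#' @param radius_px nucleus radius (default 6 px).
#' @param positive_fraction probability that a nucleus is marker-positive.
#' @param overlap_fraction fraction of nuclei placed as touching partners.
#' @param contrast positive-nucleus marker intensity relative to background
#'   (default 1.3).
#' @param pixel_size_um physical scale (default 0.32).
#' @param seed RNG seed.
#' @return `list(dapi = , olig2 = ChannelImage, truth = NucleiGroundTruth)`;
#'   truth holds `centers`, `radii_px`, `positive_flags`, and the realized
#'   `positive_fraction = mean(positive_flags)`.
#' @export
gen_nuclei_image <- function(n_nuclei = 200L, shape = c(400L, 400L),
                             radius_px = 6, positive_fraction = 0.3,
                             overlap_fraction = 0.2, contrast = 1.3,
                             pixel_size_um = 0.32, seed = 1L) {
  n_nuclei <- as.integer(n_nuclei)
  set.seed(seed)
  r <- radius_px
  centers <- matrix(NA_real_, n_nuclei, 2L)
  k <- 0L; tries <- 0L
  margin <- r + 2
  while (k < n_nuclei) {
    tries <- tries + 1L
    if (tries > 200L * n_nuclei + 1000L)
      stop("infeasible nucleus packing for this field size")
    touch <- k > 0L && runif(1) < overlap_fraction
    p <- if (touch) {
      a <- runif(1, 0, 2 * pi)
      centers[sample.int(k, 1L), ] + 1.8 * r * c(sin(a), cos(a))
    } else {
      c(runif(1, 1 + margin, shape[1L] - margin),
        runif(1, 1 + margin, shape[2L] - margin))
    }
    if (p[1L] < 1 + margin || p[1L] > shape[1L] - margin ||
        p[2L] < 1 + margin || p[2L] > shape[2L] - margin) next
    if (k > 0L) {
      d2 <- (centers[seq_len(k), 1L] - p[1L])^2 +
            (centers[seq_len(k), 2L] - p[2L])^2
      if (min(d2) < (1.8 * r)^2) next
    }
    k <- k + 1L
    centers[k, ] <- p
  }
  flags <- rbinom(n_nuclei, 1L, positive_fraction) == 1L

  dapi <- matrix(30, shape[1L], shape[2L])
  for (i in seq_len(n_nuclei))
    dapi <- stamp_disk(dapi, centers[i, 1L], centers[i, 2L], r, 180)
  dapi <- pmax(dapi + matrix(rnorm(prod(shape), 0, 8), shape[1L], shape[2L]), 0)

  bg <- 100
  olig2 <- matrix(bg, shape[1L], shape[2L])
  for (i in which(flags))
    olig2 <- stamp_disk(olig2, centers[i, 1L], centers[i, 2L], r, bg * contrast)
  olig2 <- pmax(olig2 + matrix(rnorm(prod(shape), 0, 4), shape[1L], shape[2L]), 0)

  truth <- structure(list(n_nuclei = n_nuclei, centers = centers,
                          radii_px = rep(r, n_nuclei),
                          positive_flags = flags,
                          positive_fraction = mean(flags),
                          overlap_fraction = overlap_fraction,
                          contrast = contrast), class = "NucleiGroundTruth")
  list(dapi = channel_image(dapi, pixel_size_um, "DAPI"),
       olig2 = channel_image(olig2, pixel_size_um, "Olig2"),
       truth = truth)
}

#' Simulate a microglia-stain image with a known stained-area fraction
#'
#' Bright ramified shapes — random-walk skeletons dilated by a small disc —
#' are accumulated until the stained mask reaches the target fraction of the
#' field; the realized fraction is returned exactly from the ground-truth
#' mask. Foreground and background intensities are well separated so an
#' automatic threshold can recover the mask.
#'
#' @param target_fraction desired stained-area fraction, in `[0, 0.5]`.
#' @param shape field size, default `c(300, 300)`.
#' @param walk_steps steps per random-walk skeleton (default 60).
#' @param dilation_radius dilation disc radius in px (default 2).
#' @param pixel_size_um physical scale (default 0.16, x40 objective).
#' @param seed RNG seed.
#' @return `list(image = ChannelImage, realized_fraction = , mask = )`.
#' @export
gen_microglia_image <- function(target_fraction, shape = c(300L, 300L),
                                walk_steps = 60L, dilation_radius = 2L,
                                pixel_size_um = 0.16, seed = 1L) {
  if (target_fraction < 0 || target_fraction > 0.5)
    stop("'target_fraction' must be in [0, 0.5]")
  set.seed(seed)
  mask <- matrix(FALSE, shape[1L], shape[2L])
  brush <- EBImage::makeBrush(2L * dilation_radius + 1L, shape = "disc")
  while (mean(mask) < target_fraction) {
    skel <- matrix(0, shape[1L], shape[2L])
    p <- c(sample.int(shape[1L], 1L), sample.int(shape[2L], 1L))
    dir <- runif(1, 0, 2 * pi)
    for (s in seq_len(walk_steps)) {
      skel[p[1L], p[2L]] <- 1
      dir <- dir + rnorm(1, 0, 0.6)       # persistent, ramified walk
      p <- pmin(pmax(p + round(c(sin(dir), cos(dir))), 1L), shape)
      if (runif(1) < 0.05) dir <- runif(1, 0, 2 * pi)   # branch kink
    }
    blob <- EBImage::dilate(skel, brush) > 0
    mask <- mask | blob
  }
  img <- matrix(20, shape[1L], shape[2L])
  img[mask] <- 200
  img <- pmax(img + matrix(rnorm(prod(shape), 0, 8), shape[1L], shape[2L]), 0)
  list(image = channel_image(img, pixel_size_um, "Iba1-synthetic"),
       realized_fraction = mean(mask), mask = mask)
}

#' Simulate a two-channel debris/axon colocalization field
#'
#' Each red-channel debris is a bright core with a surrounding annular rim
#' (the core is the regional maximum, so red-channel focus detection lands on
#' the debris center; the rim produces the ring crossings of a line profile,
#' and the trough between core and rim stays above half-prominence, keeping
#' the red support interval contiguous); the green channel carries
#' an axon punctum per debris according to its status: `central` (at the ring
#' center), `lateral` (offset by half the ring radius), or `absent`.
#'
#' @param n_debris number of debris rings.
#' @param axon_present_fraction probability a debris has an axon
#'   (central or lateral with equal probability).
#' @param shape field size, default `c(400, 400)` (an 88 x 88 um confocal
#'   field at 0.22 um/px).
#' @param ring_radius_px rim radius (default 5 px, must be `>= 2`).
#' @param amplitude rim intensity above background (default 120).
#' @param pixel_size_um physical scale (default 0.22).
#' @param seed RNG seed.
#' @return `list(red = , green = ChannelImage, truth = ColocGroundTruth)`;
#'   truth holds `centers`, `ring_radius_px`, `axon_status` (character) and
#'   the realized `axon_present_fraction`.
#' @export
gen_coloc_image <- function(n_debris = 80L, axon_present_fraction = 0.5,
                            shape = c(400L, 400L), ring_radius_px = 5,
                            amplitude = 120, pixel_size_um = 0.22,
                            seed = 1L) {
  if (ring_radius_px < 2) stop("'ring_radius_px' must be >= 2 px")
  n_debris <- as.integer(n_debris)
  set.seed(seed)
  r0 <- ring_radius_px
  centers <- place_points(n_debris, shape, min_dist = 5 * r0,
                          margin = 3 * r0)
  present <- runif(n_debris) < axon_present_fraction
  status <- ifelse(present,
                   ifelse(runif(n_debris) < 0.5, "central", "lateral"),
                   "absent")
  red <- matrix(8, shape[1L], shape[2L])
  green <- matrix(8, shape[1L], shape[2L])
  sig_rim <- 1.2
  for (i in seq_len(n_debris)) {
    rc <- centers[i, ]
    ext <- ceiling(r0 + 4 * sig_rim)
    rr <- max(1L, floor(rc[1L] - ext)):min(shape[1L], ceiling(rc[1L] + ext))
    cc <- max(1L, floor(rc[2L] - ext)):min(shape[2L], ceiling(rc[2L] + ext))
    d <- sqrt(outer((rr - rc[1L])^2, (cc - rc[2L])^2, "+"))
    rim <- 0.6 * amplitude * exp(-(d - r0)^2 / (2 * sig_rim^2))
    core <- amplitude * exp(-d^2 / (2 * (0.6 * r0)^2))
    red[rr, cc] <- red[rr, cc] + core + rim
    if (status[i] != "absent") {
      off <- if (status[i] == "central") c(0, 0) else {
        a <- runif(1, 0, 2 * pi)
        0.5 * r0 * c(sin(a), cos(a))
      }
      green <- add_gaussian(green, rc[1L] + off[1L], rc[2L] + off[2L],
                            amplitude, 1.2)
    }
  }
  noise <- function(m) pmax(m + matrix(rnorm(prod(shape), 0, 2),
                                       shape[1L], shape[2L]), 0)
  truth <- structure(list(n_debris = n_debris, centers = centers,
                          ring_radius_px = r0, axon_status = status,
                          axon_present_fraction = mean(status != "absent")),
                     class = "ColocGroundTruth")
  list(red = channel_image(noise(red), pixel_size_um, "SMI94-red"),
       green = channel_image(noise(green), pixel_size_um, "NFL-green"),
       truth = truth)
}

#' Categorical mixture defining a synthetic EM lesion population
#'
#' Defaults are the lesion composition the census pipeline was built around:
#' roughly three quarters vacuoles, predominantly intramyelinic and in the
#' innermost myelin layers, half with an apparently intact axon, sparse
#' microglial contact, and sub-micrometre vacuole diameters (log-normal with
#' median 0.83 um).
#'
#' @param lesion_type_probs,location_probs,layer_probs,axon_status_probs
#'   named probability vectors (normalized internally; must be non-negative
#'   and sum to a positive value).
#' @param contact_prob probability a debris touches / is internalized by
#'   microglia.
#' @param diameter_meanlog,diameter_sdlog log-normal parameters of the true
#'   vacuole diameter distribution in um.
#' @param n_mice,n_lesions_per_mouse study size (default 4 mice x 200).
#' @return A list of class `LesionMixture`.
#' @export
lesion_mixture <- function(
    lesion_type_probs = c(vacuole = 0.768, myelin_whorl = 0.147, other = 0.085),
    location_probs = c(intramyelinic = 0.838, intracellular = 0.048,
                       unassigned = 0.118),
    layer_probs = c(innermost = 0.765, outermost = 0.235),
    axon_status_probs = c(intact = 0.499, degenerating = 0.2505,
                          absent = 0.2505),
    contact_prob = 0.133,
    diameter_meanlog = log(0.83), diameter_sdlog = 0.35,
    n_mice = 4L, n_lesions_per_mouse = 200L) {
  norm <- function(p) {
    if (any(p < 0) || sum(p) <= 0) stop("invalid probability vector")
    p / sum(p)
  }
  if (n_lesions_per_mouse < 1L) stop("need at least one lesion per mouse")
  structure(list(lesion_type_probs = norm(lesion_type_probs),
                 location_probs = norm(location_probs),
                 layer_probs = norm(layer_probs),
                 axon_status_probs = norm(axon_status_probs),
                 contact_prob = contact_prob,
                 diameter_meanlog = diameter_meanlog,
                 diameter_sdlog = diameter_sdlog,
                 n_mice = as.integer(n_mice),
                 n_lesions_per_mouse = as.integer(n_lesions_per_mouse)),
            class = "LesionMixture")
}

#' Draw a synthetic EM lesion annotation table
#'
#' Records are drawn independently per category axis, grouped by mouse.
#' Layer is defined only for intramyelinic lesions (`"n/a"` otherwise);
#' vacuoles carry a profile area in um^2 derived from the diameter
#' distribution.
#'
#' @param mix a [lesion_mixture()].
#' @param seed RNG seed.
#' @return data.frame with columns `mouse_id`, `field_id`, `lesion_type`,
#'   `location`, `layer`, `axon_status`, `microglia_contact`, `area_um2`.
#' @export
gen_lesion_table <- function(mix = lesion_mixture(), seed = 1L) {
  stopifnot(inherits(mix, "LesionMixture"))
  set.seed(seed)
  n <- mix$n_mice * mix$n_lesions_per_mouse
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  lesion_type <- draw(mix$lesion_type_probs)
  location <- draw(mix$location_probs)
  layer <- ifelse(location == "intramyelinic", draw(mix$layer_probs), "n/a")
  d <- rlnorm(n, mix$diameter_meanlog, mix$diameter_sdlog)
  data.frame(
    mouse_id = rep(paste0("mouse", seq_len(mix$n_mice)),
                   each = mix$n_lesions_per_mouse),
    field_id = rep(seq_len(mix$n_lesions_per_mouse), times = mix$n_mice) %/% 25L + 1L,
    lesion_type = lesion_type,
    location = location,
    layer = layer,
    axon_status = draw(mix$axon_status_probs),
    microglia_contact = ifelse(runif(n) < mix$contact_prob, "yes", "no"),
    area_um2 = ifelse(lesion_type == "vacuole", pi * d^2 / 4, NA_real_))
}

#' Random plane sections through a sphere (thin-section model)
#'
#' A random plane at signed offset `u ~ U(-1, 1)` (in units of the sphere
#' radius) through a sphere of diameter `D` produces a circular profile of
#' diameter `d = D * sqrt(1 - u^2)`. The profile median is `D * sqrt(3)/2`,
#' the analytic basis of the eccentric-sectioning correction in
#' [correct_section_median()].
#'
#' @param true_diameter sphere diameter `D` in um.
#' @param n number of sections.
#' @param seed RNG seed.
#' @return Numeric vector of `n` profile diameters.
#' @export
sample_sphere_sections <- function(true_diameter, n, seed = 1L) {
  stopifnot(n >= 1L, true_diameter > 0)
  set.seed(seed)
  u <- runif(n, -1, 1)
  true_diameter * sqrt(1 - u^2)
}

#' Simulate a paired axon/fiber diameter table
#'
#' Axon diameters are log-normal; myelin thickness is set so g sits near
#' `g_mean` with biological scatter, optionally shifted in one group.
#' Used to exercise the g-ratio scattergram and group comparison.
#'
#' @param n_per_group records per group (default 150; at least 120 intact
#'   sheaths per genotype is the design minimum).
#' @param groups group labels.
#' @param n_mice_per_group animals per group (default 4).
#' @param g_mean,g_sd target g-ratio level and scatter.
#' @param g_shift added to `g_mean` in the second group.
#' @param seed RNG seed.
#' @return data.frame with `group`, `mouse_id`, `d_axon_um`, `d_fiber_um`.
#' @export
gen_gratio_table <- function(n_per_group = 150L,
                             groups = c("control", "mutant"),
                             n_mice_per_group = 4L,
                             g_mean = 0.72, g_sd = 0.04, g_shift = 0,
                             seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_along(groups), function(gi) {
    g <- pmin(pmax(rnorm(n_per_group,
                         g_mean + if (gi == 2L) g_shift else 0, g_sd),
                   0.3), 0.95)
    d_axon <- rlnorm(n_per_group, log(0.55), 0.3)
    data.frame(group = groups[gi],
               mouse_id = paste0(groups[gi], "_m",
                                 rep_len(seq_len(n_mice_per_group), n_per_group)),
               d_axon_um = d_axon,
               d_fiber_um = d_axon / g)
  })
  do.call(rbind, out)
}
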