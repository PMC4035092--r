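#' Randomly select debris on the red channel, blind to the green channel
#'
#' Detects foci on the red channel with [detect_foci()] and samples
#' `n_per_image` of them uniformly without replacement. The function never
#' receives the green raster, so the selection is blind by construction.
#'
#' @param red red-channel [channel_image()].
#' @param n_per_image number of debris to sample.
#' @param params a [detection_params()] for the red-channel detection.
#' @param seed RNG seed for the sampling.
#' @param roi optional [polygon_roi()] restricting the detection.
#' @return Matrix of selected `(row, col)` centers. If fewer foci are
#'   detected than requested, all are returned with a warning.
#' @export
select_debris <- function(red, n_per_image, params = detection_params(),
                          seed = 1L, roi = NULL) {
  fs <- detect_foci(red, roi, params)
  co <- fs$coordinates
  if (nrow(co) <= n_per_image) {
    if (nrow(co) < n_per_image)
      warning(sprintf("only %d foci detected; returning all", nrow(co)))
    return(co)
  }
  set.seed(seed)
  co[sort(sample.int(nrow(co), n_per_image)), , drop = FALSE]
}

# nearest-pixel samples of one channel along a 1-px line through `center`
sample_line <- function(pixels, center, length_px, angle_deg) {
  t <- seq(-(length_px - 1) / 2, (length_px - 1) / 2, by = 1)
  th <- angle_deg * pi / 180
  rr <- round(center[1L] + t * sin(th))
  cc <- round(center[2L] + t * cos(th))
  inside <- rr >= 1 & rr <= nrow(pixels) & cc >= 1 & cc <= ncol(pixels)
  v <- rep(NA_real_, length(t))
  v[inside] <- pixels[cbind(rr[inside], cc[inside])]
  list(values = v, clipped = !all(inside))
}

#' Extract perpendicular two-channel line profiles at a debris center
#'
#' Two 1-pixel-wide lines (the second at +90 degrees) are drawn through the
#' center; both channels are sampled at unit steps by nearest-pixel lookup.
#' Samples falling outside the frame are dropped symmetrically (the clipping
#' is recorded).
#'
#' @param red,green [channel_image()]s of identical dimensions.
#' @param center `(row, col)` debris center.
#' @param length_px profile length in pixels.
#' @param angle_deg orientation of the first line, degrees from the +col
#'   axis (default 0; the second line is `angle_deg + 90`).
#' @return A `LineProfilePair`: list with `center`, `angle_deg`,
#'   `red_profiles`, `green_profiles` (each a list of two numeric vectors),
#'   and `clipped`.
#' @export
extract_profiles <- function(red, green, center, length_px = 40L,
                             angle_deg = 0) {
  stopifnot(inherits(red, "ChannelImage"), inherits(green, "ChannelImage"),
            all(dim(red$pixels) == dim(green$pixels)))
  if (center[1L] < 1 || center[1L] > nrow(red$pixels) ||
      center[2L] < 1 || center[2L] > ncol(red$pixels))
    stop("debris center outside the image")
  angles <- c(angle_deg, angle_deg + 90)
  rp <- lapply(angles, function(a) sample_line(red$pixels, center, length_px, a))
  gp <- lapply(angles, function(a) sample_line(green$pixels, center, length_px, a))
  clipped <- any(vapply(rp, `[[`, TRUE, "clipped"))
  trim <- function(r, g) {       # drop out-of-frame samples jointly
    keep <- !is.na(r$values) & !is.na(g$values)
    list(red = r$values[keep], green = g$values[keep])
  }
  pair <- Map(trim, rp, gp)
  structure(list(center = center, angle_deg = angle_deg,
                 red_profiles = lapply(pair, `[[`, "red"),
                 green_profiles = lapply(pair, `[[`, "green"),
                 clipped = clipped),
            class = "LineProfilePair")
}

# 1-D local maxima with topographic prominence (plateau -> middle index).
# For each peak, walk outward on both sides to the next strictly higher
# sample (or the end); the peak's bases are the minima over those walks and
# prominence = height - max(base_left, base_right).
peaks_1d <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L   # plateau scan
      if (j < n && y[j + 1L] < y[i]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    hi <- which(left > h)
    base_l <- min(left[seq.int(if (length(hi)) max(hi) else 1L, p - 1L)])
    right <- y[seq.int(p + 1L, n)]
    hi <- which(right > h)
    base_r <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    h - max(base_l, base_r)
  }, 0)
  data.frame(index = idx, height = y[idx], prominence = prom)
}

# red support: contiguous run around the center sample where the red profile
# stays at or above background + half the red peak prominence; background is
# the mean of the outer 10% of samples at each end. NULL when undefinable.
red_support <- function(red) {
  n <- length(red)
  k <- max(1L, ceiling(0.1 * n))
  bg <- mean(c(red[seq_len(k)], red[seq.int(n - k + 1L, n)]))
  prom <- max(red) - bg
  if (prom <= 0) return(NULL)               # flat or inverted profile
  thr <- bg + prom / 2
  ctr <- (n + 1L) %/% 2L
  if (red[ctr] < thr) return(NULL)          # center not under the red curve
  lo <- ctr; while (lo > 1L && red[lo - 1L] >= thr) lo <- lo - 1L
  hi <- ctr; while (hi < n && red[hi + 1L] >= thr) hi <- hi + 1L
  c(lo, hi)
}

#' Classify a debris as axon-present from its line-profile pair
#'
#' A debris is `axon_present` when, on at least one of the two lines, the
#' green profile has a local maximum of prominence at least
#' `peak_prominence` lying within the red profile curve — operationalized as
#' the half-prominence support interval of the red peak around the profile
#' center. A flat red profile yields `axon_absent` with `flat_red = TRUE`.
#' Raising `peak_prominence` can only remove calls, never add them.
#'
#' @param pair a `LineProfilePair` from [extract_profiles()].
#' @param peak_prominence minimum 1-D prominence of a qualifying green peak.
#' @return An `AxonCall`: list with `call` (`"axon_present"` /
#'   `"axon_absent"`), `supporting_line` (`"1"`, `"2"`, `"both"`, `"none"`)
#'   and `flat_red`.
#' @export
classify_axon <- function(pair, peak_prominence = 10) {
  stopifnot(inherits(pair, "LineProfilePair"))
  flat <- TRUE
  hit <- logical(2L)
  for (l in 1:2) {
    sup <- red_support(pair$red_profiles[[l]])
    if (is.null(sup)) next
    flat <- FALSE
    pk <- peaks_1d(pair$green_profiles[[l]])
    hit[l] <- any(pk$prominence >= peak_prominence &
                  pk$index >= sup[1L] & pk$index <= sup[2L])
  }
  supporting <- if (all(hit)) "both" else if (hit[1L]) "1"
                else if (hit[2L]) "2" else "none"
  structure(list(call = if (any(hit)) "axon_present" else "axon_absent",
                 supporting_line = supporting,
                 flat_red = flat),
            class = "AxonCall")
}

#' Percentage of debris classified axon-present
#'
#' @param calls list of `AxonCall`s.
#' @return `100 * n_present / n_calls`.
#' @export
axon_fraction <- function(calls) {
  if (length(calls) == 0L) stop("no calls supplied")
  100 * mean(vapply(calls, function(x) x$call == "axon_present", TRUE))
}

#' Full colocalization pass over one two-channel field
#'
#' Selects debris on the red channel ([select_debris()]), extracts
#' perpendicular profiles, classifies each debris, and reports the
#' axon-present percentage.
#'
#' @inheritParams select_debris
#' @inheritParams extract_profiles
#' @inheritParams classify_axon
#' @param green green-channel image (read only after selection).
#' @return List with `centers`, `calls` (data.frame: row, col, call,
#'   supporting_line) and `percent_axon_present`.
#' @export
coloc_field <- function(red, green, n_per_image = 20L,
                        params = detection_params(), length_px = 40L,
                        angle_deg = 0, peak_prominence = 10, seed = 1L,
                        roi = NULL) {
  centers <- select_debris(red, n_per_image, params, seed, roi)
  calls <- apply(centers, 1L, function(ctr) {
    classify_axon(extract_profiles(red, green, ctr, length_px, angle_deg),
                  peak_prominence)
  })
  df <- data.frame(row = centers[, 1L], col = centers[, 2L],
                   call = vapply(calls, `[[`, "", "call"),
                   supporting_line = vapply(calls, `[[`, "", "supporting_line"))
  list(centers = centers, calls = df,
       percent_axon_present = axon_fraction(calls))
}
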