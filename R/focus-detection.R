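#' Focus-detection parameters
#'
#' @param noise_tolerance prominence (intensity units) a regional maximum must
#'   exceed above its surroundings to count as a focus; must be positive.
#' @param exclude_border_px detections closer than this to the raster border
#'   are dropped (default 0: nothing is excluded at ROI edges).
#' @return A list of class `DetectionParams`. Connectivity is fixed at 8.
#' @export
detection_params <- function(noise_tolerance = 20, exclude_border_px = 0L) {
  if (!is.numeric(noise_tolerance) || noise_tolerance <= 0)
    stop("'noise_tolerance' must be positive")
  structure(list(noise_tolerance = noise_tolerance,
                 connectivity = 8L,
                 exclude_border_px = as.integer(exclude_border_px)),
            class = "DetectionParams")
}

#' Detect hyperintense foci by topographic prominence of local maxima
#'
#' Finds all regional maxima of the image restricted to the ROI (8-connected;
#' plateau maxima collapse to a single detection at the plateau pixel nearest
#' its centroid) and keeps those whose topographic prominence — height above
#' the highest saddle connecting the maximum to a higher one — exceeds the
#' noise tolerance. Prominence is offset-free, so foci "stand out from the
#' surroundings" regardless of a non-uniform background that defeats plain
#' thresholding. Counting and area are restricted to the ROI.
#'
#' @param img a [channel_image()].
#' @param roi a [polygon_roi()], or `NULL` to use the whole frame.
#' @param params a [detection_params()].
#' @return A `FocusSet`: list with `coordinates` (matrix of 1-based
#'   `(row, col)`), `scores` (prominence per focus), `roi_area_mm2`, and
#'   `density_per_mm2 = n / roi_area_mm2`.
#' @export
detect_foci <- function(img, roi = NULL, params = detection_params()) {
  stopifnot(inherits(img, "ChannelImage"), inherits(params, "DetectionParams"))
  shape <- dim(img$pixels)
  mask <- if (is.null(roi)) matrix(TRUE, shape[1L], shape[2L])
          else roi_mask(roi, shape)
  if (!any(mask)) stop("ROI mask is empty")
  mx <- cpp_find_maxima(img$pixels, mask)
  rng <- diff(range(img$pixels[mask]))
  if (params$noise_tolerance > rng && rng > 0)
    warning("noise tolerance exceeds the ROI dynamic range; no foci possible")
  keep <- mx$prominence > params$noise_tolerance
  if (params$exclude_border_px > 0L) {
    b <- params$exclude_border_px
    keep <- keep & mx$row > b & mx$row <= shape[1L] - b &
                   mx$col > b & mx$col <= shape[2L] - b
  }
  co <- cbind(row = mx$row[keep], col = mx$col[keep])
  area_mm2 <- sum(mask) * img$pixel_size_um^2 / 1e6
  structure(list(coordinates = co,
                 scores = mx$prominence[keep],
                 roi_area_mm2 = area_mm2,
                 density_per_mm2 = nrow(co) / area_mm2),
            class = "FocusSet")
}

#' @export
print.FocusSet <- function(x, ...) {
  cat(sprintf("FocusSet: %d foci in %.4g mm^2 (%.4g / mm^2)\n",
              nrow(x$coordinates), x$roi_area_mm2, x$density_per_mm2))
  invisible(x)
}

#' Debris density per square millimetre
#'
#' @param fs a `FocusSet` from [detect_foci()].
#' @return Foci per mm^2 (exact quotient).
#' @export
debris_density <- function(fs) {
  stopifnot(inherits(fs, "FocusSet"))
  if (fs$roi_area_mm2 <= 0) stop("ROI area must be positive")
  nrow(fs$coordinates) / fs$roi_area_mm2
}

# Greedy one-to-one matching of detections to true centers within max_dist px.
# Pairs are accepted in order of increasing distance; returns the number of
# matched pairs.
match_foci <- function(detected, truth, max_dist = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) return(0L)
  d2 <- outer(detected[, 1L], truth[, 1L], "-")^2 +
        outer(detected[, 2L], truth[, 2L], "-")^2
  ok <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(0L)
  ok <- ok[order(d2[ok]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); m <- 0L
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1L]; j <- ok[k, 2L]
    if (!used_d[i] && !used_t[j]) { used_d[i] <- used_t[j] <- TRUE; m <- m + 1L }
  }
  m
}

# Precision/recall/F1 of a detection set against true centers
detection_f1 <- function(detected, truth, max_dist = 3) {
  m <- match_foci(detected, truth, max_dist)
  nd <- nrow(detected); nt <- nrow(truth)
  precision <- if (nd > 0L) m / nd else if (nt == 0L) 1 else 0
  recall <- if (nt > 0L) m / nt else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Calibrate the noise tolerance on annotated fields
#'
#' Mirrors the practice of setting the tolerance once, from a batch of
#' annotated (here: synthetic ground-truth) images, to best discriminate foci
#' from background. For each candidate tolerance the mean F1 across the
#' calibration images is computed, with detections matched one-to-one to true
#' centers within `max_dist` pixels; the tolerance maximizing mean F1 wins,
#' ties broken toward the larger tolerance.
#'
#' Maxima and prominences are computed once per image, so the grid search
#' costs one detection pass regardless of grid size.
#'
#' @param calibration list of `list(image = ChannelImage, centers = matrix)`
#'   pairs (at least 3); `centers` are true `(row, col)` focus positions.
#' @param grid numeric vector of candidate tolerances.
#' @param max_dist matching radius in pixels (default 3).
#' @return List with `noise_tolerance` (the selected grid value), `mean_f1`
#'   (its mean F1), and `f1_by_tolerance`.
#' @export
calibrate_tolerance <- function(calibration, grid, max_dist = 3) {
  if (length(grid) == 0L) stop("empty tolerance grid")
  if (length(calibration) < 3L)
    stop("need at least 3 calibration images")
  truths <- lapply(calibration, function(ci) as.matrix(ci$centers))
  if (all(vapply(truths, nrow, 0L) == 0L))
    stop("calibration set contains no true foci")
  maxima <- lapply(calibration, function(ci) {
    m <- dim(ci$image$pixels)
    cpp_find_maxima(ci$image$pixels, matrix(TRUE, m[1L], m[2L]))
  })
  grid <- sort(as.numeric(grid))
  f1s <- vapply(grid, function(tol) {
    mean(mapply(function(mx, tr) {
      det <- cbind(mx$row, mx$col)[mx$prominence > tol, , drop = FALSE]
      detection_f1(det, tr, max_dist)[["f1"]]
    }, maxima, truths))
  }, 0)
  best <- max(f1s)
  pick <- max(which(f1s >= best - 1e-12))  # tie -> larger tolerance
  list(noise_tolerance = grid[pick], mean_f1 = f1s[pick],
       f1_by_tolerance = data.frame(tolerance = grid, mean_f1 = f1s))
}
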