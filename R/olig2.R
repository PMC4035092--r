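#' Parameters for oligodendrocyte counting
#'
#' @param margin_px isotropic enlargement of the nucleus region used for the
#'   surround intensity (default 70 px — note this is scale-dependent; use
#'   `margin_um` to give it in physical units instead).
#' @param ratio_threshold nucleus/surround mean-intensity ratio at or above
#'   which a nucleus is marker-positive (default 1.1; must be > 1).
#' @param min_nucleus_area_um2 components smaller than this are dropped as
#'   debris/noise (default 10 um^2).
#' @param surround_mode `"enlarged"` (default): the surround mean is taken
#'   over the enlarged region *including* the nucleus pixels;
#'   `"annulus"`: nucleus pixels excluded.
#' @param margin_um optional physical-units override of `margin_px`.
#' @return A list of class `Olig2Params`. DAPI binarization uses the Otsu
#'   threshold (shared with [area_fraction()]).
#' @export
olig2_params <- function(margin_px = 70L, ratio_threshold = 1.1,
                         min_nucleus_area_um2 = 10,
                         surround_mode = c("enlarged", "annulus"),
                         margin_um = NULL) {
  if (ratio_threshold <= 1) stop("'ratio_threshold' must be > 1")
  if (margin_px < 1L) stop("'margin_px' must be >= 1")
  structure(list(margin_px = as.numeric(margin_px),
                 ratio_threshold = ratio_threshold,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 surround_mode = match.arg(surround_mode),
                 margin_um = margin_um),
            class = "Olig2Params")
}

#' Segment nuclei on the DAPI channel
#'
#' Binarizes DAPI inside the ROI at the Otsu threshold, fills holes, drops
#' components below the minimum area, and splits touching nuclei by a
#' watershed on the negated distance transform (seeds at distance-transform
#' maxima, as provided by `EBImage::watershed`).
#'
#' @param dapi a [channel_image()].
#' @param roi a [polygon_roi()], or `NULL` for the whole frame.
#' @param params an [olig2_params()].
#' @return List with `labels` (integer matrix; 0 = background, labels
#'   partition the retained foreground) and `records` (data.frame, one row
#'   per nucleus: `label`, `area_um2`, intensity columns `NA` until
#'   [classify_positivity()]).
#' @export
segment_nuclei <- function(dapi, roi = NULL, params = olig2_params()) {
  stopifnot(inherits(dapi, "ChannelImage"), inherits(params, "Olig2Params"))
  mask <- if (is.null(roi)) matrix(TRUE, nrow(dapi$pixels), ncol(dapi$pixels))
          else roi_mask(roi, dim(dapi$pixels))
  vals <- dapi$pixels[mask]
  empty <- list(labels = matrix(0L, nrow(dapi$pixels), ncol(dapi$pixels)),
                records = data.frame(label = integer(0), area_um2 = numeric(0),
                                     mean_marker_intensity = numeric(0),
                                     surrounding_intensity = numeric(0),
                                     positivity_ratio = numeric(0),
                                     is_positive = logical(0)))
  if (length(unique(vals)) < 2L) return(empty)
  thr <- otsu_threshold(dapi, roi)
  bin <- (dapi$pixels > thr) & mask
  if (!any(bin)) return(empty)
  bin <- EBImage::fillHull(EBImage::Image(bin * 1))
  dm <- EBImage::distmap(bin)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  min_px <- params$min_nucleus_area_um2 / dapi$pixel_size_um^2
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(empty)
  relab <- labels
  relab[labels > 0] <- match(labels[labels > 0], ids)
  storage.mode(relab) <- "integer"
  n <- length(ids)
  records <- data.frame(label = seq_len(n),
                        area_um2 = tabulate(relab[relab > 0], n) *
                          dapi$pixel_size_um^2,
                        mean_marker_intensity = NA_real_,
                        surrounding_intensity = NA_real_,
                        positivity_ratio = NA_real_,
                        is_positive = NA)
  list(labels = relab, records = records)
}

#' Classify nuclei as marker-positive by the surround-ratio rule
#'
#' For each nucleus the marker-channel mean is compared with the mean over
#' the nucleus region enlarged isotropically by `margin_px` (clipped to the
#' frame; by default the enlarged region includes the nucleus pixels).
#' A nucleus is positive when its mean intensity is at least
#' `ratio_threshold` times the surround mean — a ratio exactly at the
#' threshold counts as positive. The rule is scale-free: multiplying the
#' marker channel by any positive constant changes no call.
#'
#' @param seg result of [segment_nuclei()].
#' @param olig2 marker-channel [channel_image()] (same dimensions as DAPI).
#' @param params an [olig2_params()].
#' @return `seg$records` with intensity columns and `is_positive` filled.
#' @export
classify_positivity <- function(seg, olig2, params = olig2_params()) {
  stopifnot(inherits(olig2, "ChannelImage"), inherits(params, "Olig2Params"))
  labels <- seg$labels
  if (!all(dim(labels) == dim(olig2$pixels)))
    stop("label raster and marker image dimensions differ")
  rec <- seg$records
  if (nrow(rec) == 0L) return(rec)
  margin <- if (!is.null(params$margin_um))
    params$margin_um / olig2$pixel_size_um else params$margin_px
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  by_lab <- split(idx, labels[idx])
  for (k in seq_len(nrow(rec))) {
    pix <- by_lab[[as.character(rec$label[k])]]
    pr <- (pix - 1L) %% nr + 1L
    pc <- (pix - 1L) %/% nr + 1L
    rec$mean_marker_intensity[k] <- mean(olig2$pixels[pix])
    # enlarged region: pixels within 'margin' of the nucleus, via a distance
    # map of the nucleus complement on a margin-padded crop
    m <- ceiling(margin)
    rr <- max(1L, min(pr) - m):min(nr, max(pr) + m)
    cc <- max(1L, min(pc) - m):min(nc, max(pc) + m)
    nuc <- matrix(0, length(rr), length(cc))
    nuc[cbind(pr - rr[1L] + 1L, pc - cc[1L] + 1L)] <- 1
    dm <- EBImage::imageData(EBImage::distmap(1 - nuc))
    enlarged <- dm <= margin
    if (params$surround_mode == "annulus") enlarged <- enlarged & nuc == 0
    sub <- olig2$pixels[rr, cc, drop = FALSE]
    rec$surrounding_intensity[k] <- mean(sub[enlarged])
  }
  if (any(rec$surrounding_intensity <= 0))
    stop("surround intensity must be positive to form a ratio")
  rec$positivity_ratio <- rec$mean_marker_intensity / rec$surrounding_intensity
  rec$is_positive <- rec$positivity_ratio >= params$ratio_threshold
  rec
}

#' Density of marker-positive nuclei per square millimetre
#'
#' @param records classified records from [classify_positivity()].
#' @param roi the global region the counts refer to.
#' @param pixel_size_um physical scale of the analyzed image.
#' @return Positives per mm^2 (exact quotient over the ROI polygon area).
#' @export
olig2_density <- function(records, roi, pixel_size_um) {
  area_mm2 <- roi_area_px(roi) * pixel_size_um^2 / 1e6
  if (area_mm2 <= 0) stop("ROI area must be positive")
  sum(records$is_positive) / area_mm2
}
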