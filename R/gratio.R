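#' g-ratio of a myelinated fiber
#'
#' `g = d_axon / d_fiber`, the axon diameter over the total outer myelin
#' sheath diameter. Vectorized; unit-free (any common diameter unit).
#' Records with `d_axon >= d_fiber` or non-positive diameters are rejected
#' as measurement errors.
#'
#' @param d_axon,d_fiber paired diameters (same units).
#' @return Numeric vector of g-ratios in (0, 1).
#' @examples
#' compute_gratio(0.6, 1.0)  # 0.6
#' @export
compute_gratio <- function(d_axon, d_fiber) {
  if (length(d_axon) != length(d_fiber)) stop("diameter vectors differ in length")
  if (any(d_fiber <= 0) || any(d_axon <= 0))
    stop("diameters must be positive")
  if (any(d_axon >= d_fiber))
    stop("d_axon >= d_fiber: rejected as a measurement error")
  d_axon / d_fiber
}

#' Equivalent-circle diameters from concentric mask areas
#'
#' Extension of the direct-measurement workflow: axon and fiber diameters are
#' taken as equivalent-circle diameters `2 * sqrt(area / pi)` of segmented
#' cross-section masks.
#'
#' @param axon_area_um2,fiber_area_um2 paired profile areas.
#' @return data.frame with `d_axon_um`, `d_fiber_um`, `g`.
#' @export
gratio_from_areas <- function(axon_area_um2, fiber_area_um2) {
  d_a <- equivalent_diameter(axon_area_um2)
  d_f <- equivalent_diameter(fiber_area_um2)
  data.frame(d_axon_um = d_a, d_fiber_um = d_f,
             g = compute_gratio(d_a, d_f))
}

#' Binned g-ratio-versus-axon-diameter summary per group
#'
#' Equal-width bins over the pooled axon-diameter range; per bin and group,
#' the mean g, its SEM and n (empty bins keep `n = 0` with `NA` mean). The
#' companion scattergram data are the records themselves; a formal group
#' comparison on per-mouse mean g is available via [t_test_groups()].
#'
#' @param records data.frame with columns `group`, `mouse_id`, `d_axon_um`,
#'   `d_fiber_um` (e.g. from [gen_gratio_table()] or [read_gratio_table()]).
#' @param n_bins number of diameter bins (default 6).
#' @param min_per_group records-per-group floor below which a warning is
#'   issued (default 120, the design minimum of intact sheaths per genotype).
#' @return List with `records` (g attached), `bins` (data.frame: group, bin,
#'   bin_mid_um, n, mean_g, sem_g).
#' @export
gratio_scatter <- function(records, n_bins = 6L, min_per_group = 120L) {
  records$g <- compute_gratio(records$d_axon_um, records$d_fiber_um)
  cnt <- table(records$group)
  if (any(cnt < min_per_group))
    warning("fewer than ", min_per_group, " records in group(s): ",
            paste(names(cnt)[cnt < min_per_group], collapse = ", "))
  rng <- range(records$d_axon_um)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)   # all diameters identical
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- cut(records$d_axon_um, brk, include.lowest = TRUE, labels = FALSE)
  groups <- unique(records$group)
  out <- expand.grid(group = groups, bin = seq_len(n_bins),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$bin_mid_um <- (brk[out$bin] + brk[out$bin + 1L]) / 2
  stats <- mapply(function(g, b) {
    v <- records$g[records$group == g & bin == b]
    c(n = length(v), mean_g = if (length(v)) mean(v) else NA_real_,
      sem_g = if (length(v) > 1L) sd(v) / sqrt(length(v))
              else if (length(v) == 1L) NA_real_ else NA_real_)
  }, out$group, out$bin)
  out$n <- as.integer(stats["n", ])
  out$mean_g <- stats["mean_g", ]
  out$sem_g <- stats["sem_g", ]
  list(records = records, bins = out)
}

#' Read a paired-diameter CSV
#'
#' Expected columns: `group`, `mouse_id`, `d_axon_um`, `d_fiber_um`.
#' @param path CSV path.
#' @export
read_gratio_table <- function(path) {
  if (!file.exists(path)) stop("g-ratio table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "mouse_id", "d_axon_um", "d_fiber_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
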