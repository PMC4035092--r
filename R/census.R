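## EM lesion-census statistics: categorical fractions per mouse, vacuole size
## distribution with the eccentric-sectioning correction, unbiased
## counting-frame densities, and microglia-contact bookkeeping. The animal is
## the statistical unit throughout: percentages are computed per mouse first,
## then averaged (mean +/- SEM across mice).

# per-mouse percentages for one categorical axis -> mean +/- SEM across mice
#' Per-mouse category percentages for one census axis
#'
#' For every mouse, each category's share of that mouse's lesions (in %,
#' summing to 100 exactly); categories absent in a mouse contribute 0%.
#' Percentages are then averaged across mice with their SEM.
#'
#' @param records lesion table (see [gen_lesion_table()] for the schema).
#' @param axis column name: one of `"lesion_type"`, `"location"`, `"layer"`,
#'   `"axon_status"`, `"microglia_contact"`.
#' @param drop categories excluded before forming percentages (default
#'   `"n/a"`, so e.g. the layer axis is conditioned on intramyelinic
#'   lesions).
#' @return List with `per_mouse` (mouse x category percentage matrix) and
#'   `summary` (data.frame: category, mean_pct, sem_pct, n_mice).
#' @export
census_fractions <- function(records, axis, drop = "n/a") {
  if (nrow(records) == 0L) stop("empty lesion table")
  if (!axis %in% names(records)) stop("unknown census axis: ", axis)
  rec <- records[!records[[axis]] %in% drop, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records on axis ", axis)
  tab <- table(rec$mouse_id, rec[[axis]])
  pct <- 100 * sweep(unclass(tab), 1L, rowSums(tab), "/")
  summ <- data.frame(
    category = colnames(pct),
    mean_pct = colMeans(pct),
    sem_pct = apply(pct, 2L, function(x)
      if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_),
    n_mice = nrow(pct), row.names = NULL)
  list(per_mouse = pct, summary = summ)
}

#' Equivalent-circle diameter of a profile area
#'
#' `d = 2 * sqrt(area / pi)` — the diameter of the circle with the same area.
#' Strictly increasing in area.
#'
#' @param area_um2 profile area(s), um^2; must be positive.
#' @return Diameter(s) in um.
#' @examples
#' equivalent_diameter(pi / 4)  # 1
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive")
  2 * sqrt(area_um2 / pi)
}

#' Vacuole size distribution
#'
#' Equivalent diameters of all vacuole profiles, binned per mouse and pooled;
#' reports the pooled median and the fraction of profiles below 1 um.
#'
#' @param records lesion table; rows with `lesion_type == "vacuole"` and a
#'   positive `area_um2` are used.
#' @param bin_width_um histogram bin width (default 0.25 um).
#' @return List with `diameters_um`, `median_um`, `fraction_below_1um`,
#'   `histogram` (pooled data.frame: bin_low_um, bin_high_um, count) and
#'   `per_mouse_counts` (mouse x bin matrix).
#' @export
size_distribution <- function(records, bin_width_um = 0.25) {
  v <- records[records$lesion_type == "vacuole" & !is.na(records$area_um2), ,
               drop = FALSE]
  if (nrow(v) == 0L) stop("no vacuole areas in the table")
  d <- equivalent_diameter(v$area_um2)
  brk <- seq(0, ceiling(max(d) / bin_width_um) * bin_width_um,
             by = bin_width_um)
  bin <- cut(d, brk, include.lowest = TRUE, labels = FALSE)
  hist <- data.frame(bin_low_um = brk[-length(brk)], bin_high_um = brk[-1L],
                     count = tabulate(bin, length(brk) - 1L))
  per_mouse <- table(v$mouse_id, bin)
  list(diameters_um = d, median_um = median(d),
       fraction_below_1um = mean(d < 1),
       histogram = hist, per_mouse_counts = unclass(per_mouse))
}

#' Correct an observed median profile diameter for eccentric sectioning
#'
#' Random thin sections through spheres under-represent true diameters
#' (profiles `d = D * sqrt(1 - u^2)`); for monodisperse spheres the median
#' profile is `sqrt(3)/2` of the true diameter, so the default correction
#' multiplies the observed median by `2 / sqrt(3) ~ 1.1547` (the model whose
#' oracle is [sample_sphere_sections()]). The factor is configurable and is
#' always part of the return value.
#'
#' @param observed_median_um observed median profile diameter, um.
#' @param correction_factor multiplicative factor (default `2/sqrt(3)`).
#' @return List with `estimated_true_diameter_um`, `observed_median_um`,
#'   `correction_factor`.
#' @export
correct_section_median <- function(observed_median_um,
                                   correction_factor = 2 / sqrt(3)) {
  if (observed_median_um <= 0) stop("observed median must be positive")
  if (correction_factor <= 0) stop("correction factor must be positive")
  list(estimated_true_diameter_um = observed_median_um * correction_factor,
       observed_median_um = observed_median_um,
       correction_factor = correction_factor)
}

#' Count points into an unbiased counting frame
#'
#' The frame is a square of area `frame_area_um2` with its left and bottom
#' borders forbidden: a point is counted iff `x0 < x <= x0 + side` and
#' `y0 < y <= y0 + side`. Tiling a plane with such frames counts every point
#' exactly once.
#'
#' @param points matrix/data.frame with columns `(x, y)` in um.
#' @param x0,y0 frame lower-left corner, um.
#' @param frame_area_um2 frame area (default 400 um^2).
#' @return Integer count.
#' @export
frame_count <- function(points, x0, y0, frame_area_um2 = 400) {
  side <- sqrt(frame_area_um2)
  p <- as.matrix(points)
  sum(p[, 1L] > x0 & p[, 1L] <= x0 + side &
      p[, 2L] > y0 & p[, 2L] <= y0 + side)
}

#' Lesion density per 1000 um^2 from counting frames
#'
#' Per-frame density is `1000 * count / frame_area_um2`; frames are averaged
#' within mouse, then across mice (mean +/- SEM, mouse as the unit).
#'
#' @param frames data.frame with columns `mouse_id`, `count`, and optionally
#'   `frame_area_um2` (default 400).
#' @return List with `per_frame`, `per_mouse` (named mean densities) and
#'   `mean`, `sem`, `n_mice` (densities per 1000 um^2).
#' @export
frame_density <- function(frames) {
  if (nrow(frames) == 0L) stop("no counting frames")
  area <- if ("frame_area_um2" %in% names(frames)) frames$frame_area_um2
          else rep(400, nrow(frames))
  if (any(area <= 0)) stop("frame area must be positive")
  dens <- 1000 * frames$count / area
  pm <- tapply(dens, frames$mouse_id, mean)
  per_mouse <- setNames(as.numeric(pm), dimnames(pm)[[1L]])
  n <- length(per_mouse)
  list(per_frame = dens, per_mouse = per_mouse,
       mean = mean(per_mouse),
       sem = if (n > 1L) sd(per_mouse) / sqrt(n) else NA_real_,
       n_mice = n)
}

#' Microglia-contact percentage of myelin debris
#'
#' Percentage of debris in contact with or internalized by microglia,
#' per mouse then mean +/- SEM across mice. Records with
#' `microglia_contact` outside `{yes, no}` are ignored.
#'
#' @param records lesion table with a `microglia_contact` column.
#' @return List with `per_mouse` (named percentages), `mean`, `sem`,
#'   `n_mice`.
#' @export
contact_fraction <- function(records) {
  rec <- records[records$microglia_contact %in% c("yes", "no"), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records with a yes/no microglia_contact")
  pm <- tapply(rec$microglia_contact == "yes", rec$mouse_id,
               function(x) 100 * mean(x))
  per_mouse <- setNames(as.numeric(pm), dimnames(pm)[[1L]])
  n <- length(per_mouse)
  list(per_mouse = per_mouse, mean = mean(per_mouse),
       sem = if (n > 1L) sd(per_mouse) / sqrt(n) else NA_real_,
       n_mice = n)
}

#' Read an EM lesion annotation CSV
#'
#' Expected columns: `mouse_id`, `lesion_type`, `location`, `layer`,
#' `axon_status`, `microglia_contact`, `area_um2` (see
#' [gen_lesion_table()]); `field_id` is optional.
#' @param path CSV path.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) stop("lesion table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "lesion_type", "location", "layer", "axon_status",
            "microglia_contact", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
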