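#' Simulate and analyze a two-group myelin-debris experiment
#'
#' End-to-end in-silico version of the debris-density comparison: per mouse,
#' `fields_per_mouse` synthetic debris fields are generated whose true focus
#' densities differ between groups by `fold` (default 3.9, with 5 mutant and
#' 8 control mice — the 20-month study design); each field is analyzed with
#' [detect_foci()] at a tolerance calibrated on separate fields, densities
#' are averaged per mouse, and the groups are compared with a Student's t
#' test on per-mouse densities.
#'
#' @param n_mutant,n_control animals per group (defaults 5 and 8).
#' @param fields_per_mouse fields analyzed per mouse (default 3).
#' @param base_foci mean foci per control field (default 15).
#' @param fold multiplicative debris excess in the mutant group (default 3.9).
#' @param shape field size in px (default `c(192, 192)`).
#' @param seed global seed; all per-field seeds derive from it.
#' @param ... further arguments passed to [gen_foci_image()].
#' @return List with `per_mouse` (data.frame: group, mouse_id, density),
#'   `test` (a `TwoGroupTest`), `noise_tolerance`, and `report`
#'   (single-row [build_report()] table).
#' @export
simulate_debris_experiment <- function(n_mutant = 5L, n_control = 8L,
                                       fields_per_mouse = 3L,
                                       base_foci = 15, fold = 3.9,
                                       shape = c(192L, 192L), seed = 1L,
                                       ...) {
  # calibrate once on a separate batch of annotated fields
  cal_seeds <- stage_seed(seed, "calibration") + seq_len(5L)
  cal <- lapply(cal_seeds, function(s) {
    f <- gen_foci_image(n_foci = 30L, shape = shape, seed = s %% 2147483647L, ...)
    list(image = f$image, centers = f$truth$centers)
  })
  tol <- calibrate_tolerance(cal, grid = seq(5, 100, by = 5))$noise_tolerance
  params <- detection_params(noise_tolerance = tol)

  groups <- c(rep("mutant", n_mutant), rep("control", n_control))
  mice <- c(paste0("mut_m", seq_len(n_mutant)),
            paste0("ctl_m", seq_len(n_control)))
  per_field <- list()
  k <- 0L
  for (i in seq_along(mice)) {
    lambda <- base_foci * if (groups[i] == "mutant") fold else 1
    for (f in seq_len(fields_per_mouse)) {
      k <- k + 1L
      s <- (stage_seed(seed, "fields") + 131L * k) %% 2147483647L
      set.seed(s)
      n_foci <- stats::rpois(1L, lambda)
      fld <- gen_foci_image(n_foci = n_foci, shape = shape, seed = s, ...)
      fs <- detect_foci(fld$image, roi = NULL, params = params)
      per_field[[k]] <- data.frame(group = groups[i], mouse_id = mice[i],
                                   density = debris_density(fs))
    }
  }
  fields <- do.call(rbind, per_field)
  per_mouse <- aggregate(density ~ group + mouse_id, fields, mean)
  tt <- t_test_groups(per_mouse$density[per_mouse$group == "mutant"],
                      per_mouse$density[per_mouse$group == "control"],
                      c("mutant", "control"))
  rep <- build_report(data.frame(measure = "debris_density_per_mm2",
                                 group = fields$group,
                                 mouse_id = fields$mouse_id,
                                 value = fields$density))
  list(per_mouse = per_mouse, test = tt, noise_tolerance = tol,
       report = rep$table)
}
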