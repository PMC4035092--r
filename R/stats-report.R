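#' Group summary: mean and SEM over per-animal values
#'
#' SEM is the sample standard deviation (n - 1 denominator) over the square
#' root of n; with a single animal the SEM is undefined and reported as `NA`,
#' not 0.
#'
#' @param values per-animal measurements.
#' @param group_label label carried into reports.
#' @return A `GroupSummary`: list with `group_label`, `n`, `mean`, `sem`.
#' @examples
#' summarize_group(c(2, 4, 6))  # mean 4, sem 2/sqrt(3)
#' @export
summarize_group <- function(values, group_label = "group") {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be a non-empty finite vector")
  n <- length(values)
  structure(list(group_label = group_label, n = n, mean = mean(values),
                 sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_),
            class = "GroupSummary")
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$group_label, x$mean,
              ifelse(is.na(x$sem), NaN, x$sem), x$n))
  invisible(x)
}

#' Two-group Student's t test with fold change
#'
#' Classical pooled-variance two-sample t test, two-sided (a Welch option is
#' provided); significance is flagged at alpha = 0.05. The fold change is
#' `mean(a) / mean(b)`. Degenerate inputs: zero pooled variance with equal
#' means gives `t = 0, p = 1`; zero pooled variance with unequal means is
#' flagged and reported as `t = +/-Inf, p = 0` (below machine epsilon).
#'
#' @param a,b per-animal measurements (each `n >= 2`).
#' @param group_labels labels for `a` and `b`.
#' @param welch use the Welch unequal-variance test instead.
#' @return A `TwoGroupTest`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significant`, `fold_change`,
#'   `summary_a`, `summary_b`, `degenerate`.
#' @export
t_test_groups <- function(a, b, group_labels = c("A", "B"), welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 animals")
  sa <- summarize_group(a, group_labels[1L])
  sb <- summarize_group(b, group_labels[2L])
  degenerate <- FALSE
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; df <- length(a) + length(b) - 2L; p <- 1
    } else {
      degenerate <- TRUE
      t <- sign(mean(a) - mean(b)) * Inf
      df <- length(a) + length(b) - 2L
      p <- 0  # below machine epsilon
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 significant = p < 0.05,
                 fold_change = mean(a) / mean(b),
                 summary_a = sa, summary_b = sb, degenerate = degenerate),
            class = "TwoGroupTest")
}

#' @export
print.TwoGroupTest <- function(x, ...) {
  cat(sprintf("%s %.4g +/- %.4g (n=%d) vs %s %.4g +/- %.4g (n=%d)\n",
              x$summary_a$group_label, x$summary_a$mean, x$summary_a$sem,
              x$summary_a$n,
              x$summary_b$group_label, x$summary_b$mean, x$summary_b$sem,
              x$summary_b$n))
  cat(sprintf("  t = %.4g, df = %g, p = %.3g%s; fold change %.3g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) " (*)" else "", x$fold_change))
  invisible(x)
}

#' Assemble the final report table across measures
#'
#' One row per measure: per-group mean +/- SEM and n, and — when exactly two
#' groups are present — the Student's t comparison with fold change. Values
#' are averaged per mouse before any test, so the animal is the statistical
#' unit. No multiple-testing correction is applied; `n_comparisons` is
#' reported so users can apply their own.
#'
#' @param measurements data.frame with columns `measure`, `group`,
#'   `mouse_id`, `value` (one row per field or per mouse; fields are
#'   averaged within mouse).
#' @return List with `table` (the report data.frame) and `n_comparisons`.
#' @export
build_report <- function(measurements) {
  need <- c("measure", "group", "mouse_id", "value")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(measurements) == 0L) stop("empty measurement table")
  rows <- lapply(split(measurements, measurements$measure), function(mm) {
    per_mouse <- aggregate(value ~ group + mouse_id, mm, mean)
    groups <- sort(unique(per_mouse$group))
    vals <- lapply(groups, function(g) per_mouse$value[per_mouse$group == g])
    names(vals) <- groups
    row <- data.frame(measure = mm$measure[1L], stringsAsFactors = FALSE)
    for (g in groups) {
      s <- summarize_group(vals[[g]], g)
      row[[paste0("mean_", g)]] <- s$mean
      row[[paste0("sem_", g)]] <- s$sem
      row[[paste0("n_", g)]] <- s$n
    }
    if (length(groups) == 2L &&
        all(vapply(vals, length, 0L) >= 2L)) {
      tt <- t_test_groups(vals[[1L]], vals[[2L]], groups)
      row$t <- tt$t_statistic
      row$df <- tt$degrees_of_freedom
      row$p <- tt$p_value
      row$fold_change <- tt$fold_change
      row$significant <- tt$significant
    }
    row
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    r[all_names]
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       n_comparisons = sum(!is.na(tab$p)))
}

#' @importFrom stats aggregate
NULL
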