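# internal worker so the exported function can take a `mean_center`
# argument without shadowing the function of the same name
.mean_center <- function(tbl) {
  grand <- mean(tbl$y)
  subj_means <- stats::ave(tbl$y, tbl$subject, FUN = mean)
  tbl$y <- tbl$y - subj_means + grand
  tbl
}

#' Shift every subject's mean to the grand mean
#'
#' Replaces each y by `y - m_s + G`, where `m_s` is the subject's mean over
#' its own observations and `G` the grand mean of all observations. After
#' centering every subject's mean equals `G` exactly; each subject's
#' internal trajectory shape and variance are unchanged. Useful before
#' trend testing when baselines differ between individuals (body weight,
#' starting diversity, ...).
#'
#' @param tbl a `long_table`.
#' @return the centered `long_table`.
#' @export
mean_center <- function(tbl) .mean_center(tbl)

#' Signed area between a curve and a flat baseline at its start
#'
#' The trend statistic: the signed sum over grid points of
#' `curve - baseline_value`, with the baseline the zero-slope line through
#' the curve's first grid value. A trajectory that does not meaningfully
#' increase or decrease stays near its own start, so the area stays small;
#' a monotone trend accumulates signed area whose sign is the trend
#' direction.
#'
#' @param curve numeric vector: the spline evaluated on an even grid, no
#'   missing values.
#' @param baseline_value baseline height; defaults to the first grid value.
#' @return the signed area.
#' @export
trend_area <- function(curve, baseline_value = curve[[1]]) {
  if (!all(is.finite(curve))) stop("curve contains non-finite values")
  sum(curve - baseline_value)
}

#' Non-zero trend test for one group's longitudinal response
#'
#' Fits a loess spline to the pooled observations of one group, measures
#' the signed area between the spline and a flat baseline anchored at the
#' spline's start, and compares its magnitude to a null distribution
#' obtained by permuting each subject's responses across that subject's
#' own time points. Each permuted replicate is treated exactly like the
#' observed data: its spline is refit and its area measured against its
#' own start-point baseline. The p-value is two-sided (on absolute areas,
#' ties counting toward the null).
#'
#' @inheritParams permuspliner
#' @param category,group optionally subset `data` to rows whose `category`
#'   equals `group` before testing (the test itself is single-group).
#' @param mean_center if `TRUE`, shift each subject's mean to the grand
#'   mean first (see [mean_center()]); off by default.
#' @param perms number of within-subject permutations (default 999).
#' @param ints number of grid points along the observed x range
#'   (default 1000).
#' @return a `trendyspliner_result`: list with `p_value` (two-sided),
#'   `observed_area` (signed; its sign is the trend direction),
#'   `permuted_areas`, `spline` (list `x`, `y`), `baseline_value`,
#'   `direction`, `perm_curves`, `params`.
#' @examples
#' tbl <- simulate_trend(slope = 2, noise_sd = 0.5, seed = 1)
#' res <- trendyspliner(tbl, perms = 99, ints = 100, seed = 2)
#' res$p_value
#' @export
trendyspliner <- function(data, xvar = "x", yvar = "y", cases = "subject",
                          category = NULL, group = NULL,
                          perms = 999, ints = 1000,
                          span = 0.75, degree = 2, cut_low = 0,
                          mean_center = FALSE, seed = NULL,
                          retain_perm_curves = 100, quiet = TRUE) {
  stopifnot(perms >= 1, ints >= 2)
  tbl <- as_long_table(data, cases, xvar, yvar,
                       category_cols = category, quiet = quiet)
  if (!is.null(category) && !is.null(group)) {
    keep <- trimws(tbl[[category]]) == trimws(group)
    if (!any(keep)) {
      stop("group label '", group, "' not present in category '",
           category, "'")
    }
    tbl <- structure(tbl[keep, , drop = FALSE],
                     class = c("long_table", "data.frame"))
    rownames(tbl) <- NULL
  }
  if (cut_low > 0) tbl <- filter_low_prevalence(tbl, cut_low)
  if (isTRUE(mean_center)) tbl <- .mean_center(tbl)

  model <- fit_loess(tbl$x, tbl$y, span, degree)
  grid <- seq(model$x_min, model$x_max, length.out = ints)
  curve <- predict_loess(model, grid)
  observed_area <- trend_area(curve)

  n_retain <- min(retain_perm_curves, perms)
  perm_areas <- numeric(perms)
  curves <- if (n_retain > 0) vector("list", n_retain) else list()

  with_seed(seed, {
    for (i in seq_len(perms)) {
      pt <- permute_within_subject(tbl)
      pm <- fit_loess(pt$x, pt$y, span, degree)
      pc <- predict_loess(pm, grid)
      perm_areas[i] <- trend_area(pc)
      if (i <= n_retain) {
        curves[[i]] <- data.frame(perm = i, x = grid, y = pc)
      }
    }
  })

  p_value <- (sum(abs(perm_areas) >= abs(observed_area)) + 1) / (perms + 1)
  direction <- if (observed_area > 0) "increasing"
               else if (observed_area < 0) "decreasing"
               else "none"

  structure(list(
    p_value = p_value,
    observed_area = observed_area,
    permuted_areas = perm_areas,
    spline = list(x = grid, y = curve),
    baseline_value = curve[[1]],
    direction = direction,
    n_subjects = length(unique(tbl$subject)),
    perm_curves = if (n_retain > 0) do.call(rbind, curves) else NULL,
    params = list(perms = perms, ints = ints, span = span, degree = degree,
                  cut_low = cut_low, mean_center = isTRUE(mean_center),
                  seed = seed)
  ), class = "trendyspliner_result")
}

#' @export
print.trendyspliner_result <- function(x, ...) {
  cat("Single-group non-zero trend permutation test\n")
  cat("  subjects:", x$n_subjects, "  permutations:",
      length(x$permuted_areas), "\n")
  cat("  observed signed area:", format(x$observed_area, digits = 6),
      "(", x$direction, ")\n")
  cat("  two-sided p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
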