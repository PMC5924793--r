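# Per-subject smoothers with graceful degradation: loess at the requested
# degree when the subject has enough distinct x values, then degree 1, then
# straight-line interpolation between the subject's own points. Subjects
# with < 2 distinct x cannot define a curve and are dropped with a warning.
fit_subject_splines <- function(tbl, span = 0.75, degree = 2) {
  curves <- list()
  fallback_subject <- character()
  fallback_method <- character()
  dropped <- character()
  for (s in sort(unique(tbl$subject))) {
    d <- tbl[tbl$subject == s, , drop = FALSE]
    ndx <- length(unique(d$x))
    if (ndx < 2) {
      dropped <- c(dropped, s)
      next
    }
    cur <- NULL
    method <- "loess"
    for (deg in seq(degree, 1)) {
      if (ndx >= deg + 2) {
        cur <- list(kind = "loess",
                    model = fit_loess(d$x, d$y, span, deg))
        if (deg < degree) method <- paste0("degree_", deg)
        break
      }
    }
    if (is.null(cur)) {
      cur <- list(kind = "linear", x = d$x, y = d$y,
                  x_min = min(d$x), x_max = max(d$x))
      method <- "linear"
    }
    curves[[s]] <- cur
    if (method != "loess") {
      fallback_subject <- c(fallback_subject, s)
      fallback_method <- c(fallback_method, method)
    }
  }
  if (length(dropped) > 0) {
    warning("dropped subject(s) with fewer than 2 distinct x values: ",
            paste(dropped, collapse = ", "))
  }
  list(curves = curves,
       fallbacks = data.frame(subject = fallback_subject,
                              method = fallback_method,
                              stringsAsFactors = FALSE),
       dropped = dropped)
}

predict_subject_curve <- function(cur, grid) {
  if (cur$kind == "loess") {
    predict_loess(cur$model, grid)
  } else {
    # linear interpolation within the subject's own range only; duplicate
    # x values are averaged
    stats::approx(cur$x, cur$y, xout = grid, ties = mean, rule = 1)$y
  }
}

# subject x grid matrix of interpolated values; NA outside each subject's
# own observed range (no extrapolation)
interpolate_grid <- function(curves, grid) {
  if (length(curves) < 1) stop("no subject curves to interpolate")
  out <- t(vapply(curves, predict_subject_curve, numeric(length(grid)),
                  grid = grid))
  rownames(out) <- names(curves)
  out
}

# guarded two-sample test at one grid point
two_sample_p <- function(a, b, method) {
  if (length(unique(c(a, b))) == 1L) return(1)
  if (method == "mann_whitney") {
    use_exact <- length(a) <= 8 && length(b) <= 8 &&
      !anyDuplicated(c(a, b))
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)$p.value
    )
  } else {
    tryCatch(
      suppressWarnings(stats::t.test(a, b)$p.value),
      error = function(e) NA_real_
    )
  }
}

interval_tests <- function(mat, groups, grid, test_density, method,
                           labels) {
  subj <- rownames(mat)
  in1 <- subj %in% names(groups)[groups == labels[1]]
  in2 <- subj %in% names(groups)[groups == labels[2]]
  n <- length(grid)
  p_values <- rep(NA_real_, n)
  n_group1 <- integer(n)
  n_group2 <- integer(n)
  for (j in seq_len(n)) {
    v <- mat[, j]
    a <- v[in1 & !is.na(v)]
    b <- v[in2 & !is.na(v)]
    n_group1[j] <- length(a)
    n_group2[j] <- length(b)
    if (length(a) >= test_density && length(b) >= test_density) {
      p_values[j] <- two_sample_p(a, b, method)
    }
  }
  data.frame(x = grid, p_value = p_values,
             n_group1 = n_group1, n_group2 = n_group2)
}

#' Interval-wise two-group test along the time axis
#'
#' Localizes where two groups diverge. Each subject is summarized by its
#' own loess spline (filling gaps across its time series), all splines are
#' interpolated onto a common grid spanning the union of subject ranges —
#' never extrapolated beyond a subject's own first and last observation —
#' and at every grid point the two groups' interpolated values are compared
#' with a two-sample test. A p-value is reported only where both groups
#' have at least `test_density` contributing subjects; elsewhere the
#' subject counts are still recorded. No multiplicity adjustment is
#' applied: all raw p-values are returned so callers can adjust (e.g. with
#' [stats::p.adjust()]).
#'
#' @inheritParams permuspliner
#' @param ints number of grid intervals (default 100).
#' @param test_density minimum subjects per group at a grid point for its
#'   test to run (default 3, minimum 2).
#' @param interval_test `"mann_whitney"` (default; exact when both groups
#'   have at most 8 untied values, tie-corrected normal approximation
#'   otherwise) or `"welch_t"`.
#' @return a `sliding_result`: list with `table` (data.frame `x`,
#'   `p_value`, `n_group1`, `n_group2`), `subject_matrix` (subject x grid
#'   interpolated values), `groups` (subject -> label), `fallbacks`,
#'   `dropped`, `params`.
#' @examples
#' tbl <- simulate_perturbation_study(magnitude = 4, seed = 1)
#' res <- sliding_spliner(tbl, category = "condition")
#' head(res$table)
#' @export
sliding_spliner <- function(data, xvar = "x", yvar = "y",
                            category = "condition",
                            group1 = NULL, group2 = NULL, cases = "subject",
                            ints = 100, test_density = 3,
                            span = 0.75, degree = 2, cut_low = 0,
                            interval_test = c("mann_whitney", "welch_t"),
                            quiet = TRUE) {
  interval_test <- match.arg(interval_test)
  stopifnot(ints >= 2)
  if (test_density < 2) {
    stop("test_density must be at least 2 (no two-sample test below 2)")
  }
  tbl <- as_long_table(data, cases, xvar, yvar, category, quiet = quiet)
  if (cut_low > 0) tbl <- filter_low_prevalence(tbl, cut_low)
  if (is.null(group1) || is.null(group2)) {
    labs <- unique(tbl[[category]])
    if (length(labs) != 2) {
      stop("category '", category, "' has ", length(labs),
           " labels; specify group1 and group2")
    }
    group1 <- labs[1]
    group2 <- labs[2]
  }
  pair <- split_groups(tbl, category, group1, group2)
  t1 <- pair$group1_table
  t2 <- pair$group2_table
  all_rows <- rbind(as.data.frame(t1), as.data.frame(t2))
  groups <- c(stats::setNames(rep(pair$group1, length(unique(t1$subject))),
                              unique(t1$subject)),
              stats::setNames(rep(pair$group2, length(unique(t2$subject))),
                              unique(t2$subject)))

  fits <- fit_subject_splines(all_rows, span, degree)
  if (length(fits$curves) < 2) {
    stop("fewer than 2 subjects support a curve; cannot test")
  }
  rng <- vapply(fits$curves, function(cur) {
    if (cur$kind == "loess") c(cur$model$x_min, cur$model$x_max)
    else c(cur$x_min, cur$x_max)
  }, numeric(2))
  grid <- seq(min(rng[1, ]), max(rng[2, ]), length.out = ints)
  mat <- interpolate_grid(fits$curves, grid)
  tab <- interval_tests(mat, groups, grid, test_density, interval_test,
                        c(pair$group1, pair$group2))

  if (!quiet && nrow(fits$fallbacks) > 0) {
    message(nrow(fits$fallbacks), " subject spline(s) used a fallback fit")
  }

  structure(list(
    table = tab,
    subject_matrix = mat,
    groups = groups[rownames(mat)],
    category = pair$category,
    group_labels = c(pair$group1, pair$group2),
    fallbacks = fits$fallbacks,
    dropped = fits$dropped,
    params = list(ints = ints, test_density = test_density, span = span,
                  degree = degree, cut_low = cut_low,
                  interval_test = interval_test)
  ), class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  tested <- sum(!is.na(x$table$p_value))
  cat("Interval-wise two-group spline test\n")
  cat("  groups: ", x$group_labels[1], " vs ", x$group_labels[2], " on '",
      x$category, "'\n", sep = "")
  cat("  grid points:", nrow(x$table), " tested:", tested,
      " (test_density =", x$params$test_density, ")\n")
  if (tested > 0) {
    i <- which.min(x$table$p_value)
    cat("  minimum p-value:", format(x$table$p_value[i], digits = 4),
        "at x =", format(x$table$x[i], digits = 4), "\n")
  }
  invisible(x)
}
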