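#' Absolute area between two interpolated curves
#'
#' The two-group test statistic: the sum over shared grid points of
#' `|y1 - y2|`. Grid points where either curve is missing are excluded
#' pairwise; at least 2 shared points are required. Because the grid is
#' evenly spaced the sum is proportional to the Riemann integral of the
#' absolute difference; the statistic therefore scales with the number of
#' interpolation points, but the p-value does not (observed and permuted
#' statistics share the grid size).
#'
#' @param y1,y2 numeric vectors: the two curves evaluated on the same grid.
#' @return non-negative group distance.
#' @export
group_distance <- function(y1, y2) {
  if (length(y1) != length(y2)) {
    stop("curves must be evaluated on the same grid")
  }
  ok <- is.finite(y1) & is.finite(y2)
  if (sum(ok) < 2) {
    stop("no overlap: fewer than 2 shared grid points between the curves")
  }
  sum(abs(y1[ok] - y2[ok]))
}

#' Overall two-group difference test for longitudinal trajectories
#'
#' Fits one loess spline per group on all of that group's observations
#' pooled across subjects, measures the absolute area between the two
#' splines over a shared grid spanning the intersection of the groups' x
#' ranges, and compares it to a null distribution obtained by shuffling
#' which subject belongs to which group (group sizes preserved, each
#' subject's trajectory kept intact). Permutations in which a shuffled
#' group falls below `cut_sparse` observations or cannot be fit are
#' discarded and redrawn, keeping the number of permutations constant; the
#' redraw count is reported.
#'
#' @param data a data.frame or `long_table` in long format.
#' @param xvar,yvar,cases names of the independent-axis, response, and
#'   subject columns.
#' @param category name of the grouping column.
#' @param group1,group2 the two labels to compare; if `NULL` and the
#'   category has exactly two labels, those are used.
#' @param perms number of label permutations (default 999, giving a
#'   p-value floor of 0.001).
#' @param ints number of interpolation points along the shared grid
#'   (default 1000).
#' @param test_direction `"more"` (default) tests whether the groups differ
#'   more than expected by chance; `"less"` tests for smaller-than-chance
#'   differences.
#' @param cut_low drop subjects with `<= cut_low` observations
#'   (see [filter_low_prevalence()]).
#' @param cut_sparse minimum total observations for a group spline to be
#'   fit (floor 4: a degree-2 local fit is underdetermined below 4 points).
#' @param span,degree loess parameters (see [fit_loess()]).
#' @param seed optional integer seed; fixes the permutation stream.
#' @param retain_perm_curves how many permuted spline pairs to keep for
#'   plotting (default 100; bounds memory).
#' @param quiet suppress progress messages.
#' @return a `permuspliner_result`: list with `p_value`,
#'   `observed_distance`, `permuted_distances`, `direction`, `spline1`,
#'   `spline2` (each a list `x`, `y`), `category`, `groups`,
#'   `n_subjects_per_group`, `redraws`, `perm_curves`, `params`.
#' @examples
#' tbl <- simulate_perturbation_study(magnitude = 4, seed = 1)
#' res <- permuspliner(tbl, category = "condition", perms = 99,
#'                     ints = 100, seed = 2)
#' res$p_value
#' @export
permuspliner <- function(data, xvar = "x", yvar = "y",
                         category = "condition",
                         group1 = NULL, group2 = NULL, cases = "subject",
                         perms = 999, ints = 1000,
                         test_direction = c("more", "less"),
                         cut_low = 0, cut_sparse = 4,
                         span = 0.75, degree = 2, seed = NULL,
                         retain_perm_curves = 100, quiet = TRUE) {
  test_direction <- match.arg(test_direction)
  stopifnot(perms >= 1, ints >= 2)
  if (cut_sparse < 4) stop("cut_sparse must be at least 4")
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
  group1 <- pair$group1
  group2 <- pair$group2
  t1 <- pair$group1_table
  t2 <- pair$group2_table
  for (gt in list(list(t1, group1), list(t2, group2))) {
    if (nrow(gt[[1]]) < cut_sparse) {
      stop("group '", gt[[2]], "' has ", nrow(gt[[1]]),
           " observations, fewer than cut_sparse = ", cut_sparse)
    }
  }

  fit_pair <- function(x1, y1v, x2, y2v) {
    m1 <- fit_loess(x1, y1v, span, degree)
    m2 <- fit_loess(x2, y2v, span, degree)
    lo <- max(m1$x_min, m2$x_min)
    hi <- min(m1$x_max, m2$x_max)
    if (!(lo < hi)) stop("no overlap between the groups' x ranges")
    grid <- seq(lo, hi, length.out = ints)
    g1y <- predict_loess(m1, grid)
    g2y <- predict_loess(m2, grid)
    list(grid = grid, y1 = g1y, y2 = g2y, dist = group_distance(g1y, g2y))
  }

  obs <- fit_pair(t1$x, t1$y, t2$x, t2$y)

  # permutation engine: subjects sorted so the draw sequence is invariant
  # to which group is called "group1"
  all_x <- c(t1$x, t2$x)
  all_y <- c(t1$y, t2$y)
  all_subj <- c(t1$subject, t2$subject)
  subj_lab <- c(stats::setNames(rep(group1, length(unique(t1$subject))),
                                unique(t1$subject)),
                stats::setNames(rep(group2, length(unique(t2$subject))),
                                unique(t2$subject)))
  subj_lab <- subj_lab[order(names(subj_lab))]
  rows_by_subj <- split(seq_along(all_subj), all_subj)[names(subj_lab)]

  n_retain <- min(retain_perm_curves, perms)
  perm_dist <- numeric(perms)
  curves <- if (n_retain > 0) vector("list", n_retain) else list()
  redraws <- 0L

  with_seed(seed, {
    i <- 1L
    attempts <- 0L
    max_attempts <- 50L * perms + 1000L
    while (i <= perms) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("too many failed permutations (", redraws,
             " redraws); groups too sparse after shuffling")
      }
      lab <- sample(unname(subj_lab))
      i1 <- unlist(rows_by_subj[lab == group1], use.names = FALSE)
      i2 <- unlist(rows_by_subj[lab == group2], use.names = FALSE)
      if (length(i1) < cut_sparse || length(i2) < cut_sparse) {
        redraws <- redraws + 1L
        next
      }
      pp <- tryCatch(
        fit_pair(all_x[i1], all_y[i1], all_x[i2], all_y[i2]),
        error = function(e) NULL
      )
      if (is.null(pp)) {
        redraws <- redraws + 1L
        next
      }
      perm_dist[i] <- pp$dist
      if (i <= n_retain) {
        curves[[i]] <- data.frame(perm = i, x = pp$grid,
                                  y1 = pp$y1, y2 = pp$y2)
      }
      i <- i + 1L
    }
  })

  if (!quiet && redraws > 0) {
    message(redraws, " permutation(s) redrawn (sparse or unfittable groups)")
  }

  structure(list(
    p_value = empirical_p(obs$dist, perm_dist, test_direction),
    observed_distance = obs$dist,
    permuted_distances = perm_dist,
    direction = test_direction,
    spline1 = list(x = obs$grid, y = obs$y1),
    spline2 = list(x = obs$grid, y = obs$y2),
    category = category,
    groups = c(group1, group2),
    n_subjects_per_group = c(length(unique(t1$subject)),
                             length(unique(t2$subject))),
    redraws = redraws,
    perm_curves = if (n_retain > 0) do.call(rbind, curves) else NULL,
    params = list(perms = perms, ints = ints, span = span, degree = degree,
                  cut_low = cut_low, cut_sparse = cut_sparse,
                  test_direction = test_direction, seed = seed)
  ), class = "permuspliner_result")
}

#' @export
print.permuspliner_result <- function(x, ...) {
  cat("Two-group permutation spline test\n")
  cat("  groups: ", x$groups[1], " (n=", x$n_subjects_per_group[1], ") vs ",
      x$groups[2], " (n=", x$n_subjects_per_group[2], ") on '",
      x$category, "'\n", sep = "")
  cat("  observed group distance:", format(x$observed_distance, digits = 6),
      "\n")
  cat("  permutations:", length(x$permuted_distances),
      "( redraws:", x$redraws, ")\n")
  cat("  direction:", x$direction, "  p-value:",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}
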