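# shared: n_timepoints jittered positions covering [lo, hi]
jittered_times <- function(n_timepoints, lo, hi) {
  h <- (hi - lo) / (n_timepoints - 1)
  x <- seq(lo, hi, length.out = n_timepoints) +
    stats::runif(n_timepoints, -h / 2, h / 2)
  pmin(pmax(x, lo), hi)
}

#' Simulate a two-group perturbation study
#'
#' Emulates a localized-perturbation design: a control group of pure
#' Gaussian noise around a flat baseline, and a perturbed group receiving
#' one or two Gaussian bumps of amplitude `magnitude * noise_sd`. With two
#' regions the second bump has the opposite sign, making the scenario
#' qualitatively harder at low magnitude (the bumps partially cancel in any
#' overall summary). Each subject is sampled at `n_timepoints` jittered
#' positions across `x_range`. Fully determined by `seed`.
#'
#' @param n_per_group subjects per group (default 10).
#' @param n_timepoints observations per subject (default 30).
#' @param x_range numeric length-2 interval of the time axis.
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param magnitude bump amplitude as a multiple of `noise_sd`; the study
#'   design sweeps 1, 2, 4. `magnitude = 0` gives two groups drawn from
#'   identical distributions.
#' @param regions list of one or two `c(center, width)` pairs; `width` is
#'   the Gaussian bump's standard deviation on the x axis. Default: a
#'   single late-series region `c(0.7, 0.1)`.
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @return a `long_table` with groups `"control"` / `"perturbed"` in
#'   category `"condition"`.
#' @examples
#' tbl <- simulate_perturbation_study(magnitude = 2, seed = 1)
#' table(tbl$condition)
#' @export
simulate_perturbation_study <- function(n_per_group = 10,
                                        n_timepoints = 30,
                                        x_range = c(0, 1),
                                        noise_sd = 1,
                                        magnitude = 4,
                                        regions = list(c(0.7, 0.1)),
                                        seed = NULL) {
  stopifnot(n_per_group >= 2, n_timepoints >= 2, noise_sd > 0,
            magnitude >= 0, length(x_range) == 2, x_range[1] < x_range[2],
            length(regions) %in% c(1L, 2L))
  for (r in regions) {
    if (r[[2]] <= 0) stop("region width must be positive")
    if (r[[1]] < x_range[1] || r[[1]] > x_range[2]) {
      stop("region center must lie inside x_range")
    }
  }
  bump <- function(x) {
    b <- 0
    sgn <- 1
    for (r in regions) {
      b <- b + sgn * magnitude * noise_sd *
        exp(-(x - r[[1]])^2 / (2 * r[[2]]^2))
      sgn <- -sgn
    }
    b
  }
  with_seed(seed, {
    rows <- vector("list", 2 * n_per_group)
    k <- 0L
    for (g in c("control", "perturbed")) {
      for (i in seq_len(n_per_group)) {
        x <- jittered_times(n_timepoints, x_range[1], x_range[2])
        y <- stats::rnorm(n_timepoints, 0, noise_sd)
        if (g == "perturbed") y <- y + bump(x)
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = sprintf("%s_%02d",
                            if (g == "control") "ctrl" else "pert", i),
          x = x, y = y, condition = g, stringsAsFactors = FALSE)
      }
    }
    as_long_table(do.call(rbind, rows), "subject", "x", "y", "condition")
  })
}

#' Simulate an exchangeable two-group null
#'
#' Both groups are drawn from the identical noise process (flat baseline,
#' Gaussian noise), so any test comparing them should reject at its nominal
#' rate. With `staggered_entry > 0` each subject enters late and/or exits
#' early by uniform fractions of the axis, thinning data density at the
#' boundaries — the situation the sliding test's density gate exists for.
#'
#' @inheritParams simulate_perturbation_study
#' @param staggered_entry fraction of the axis (0 to < 0.5) by which
#'   subject entry and exit times are independently staggered; 0 (default)
#'   gives full-range sampling for everyone.
#' @return a `long_table` with groups `"a"` / `"b"` in category
#'   `"condition"`.
#' @export
simulate_null <- function(n_per_group = 10, n_timepoints = 30,
                          noise_sd = 1, seed = NULL, x_range = c(0, 1),
                          staggered_entry = 0) {
  stopifnot(n_per_group >= 2, n_timepoints >= 2, noise_sd > 0,
            staggered_entry >= 0, staggered_entry < 0.5)
  with_seed(seed, {
    rows <- vector("list", 2 * n_per_group)
    k <- 0L
    span_x <- x_range[2] - x_range[1]
    for (g in c("a", "b")) {
      for (i in seq_len(n_per_group)) {
        lo <- x_range[1]
        hi <- x_range[2]
        if (staggered_entry > 0) {
          lo <- lo + stats::runif(1, 0, staggered_entry) * span_x
          hi <- hi - stats::runif(1, 0, staggered_entry) * span_x
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = sprintf("%s_%02d", g, i),
          x = jittered_times(n_timepoints, lo, hi),
          y = stats::rnorm(n_timepoints, 0, noise_sd),
          condition = g, stringsAsFactors = FALSE)
      }
    }
    as_long_table(do.call(rbind, rows), "subject", "x", "y", "condition")
  })
}

#' Simulate a single group with a linear trend and subject offsets
#'
#' Subject `s` follows `y = b_s + slope * x + noise` with
#' `b_s ~ Normal(0, subject_offset_sd)`. `slope = 0` with a large offset
#' SD gives the trend null with heterogeneous baselines — the case
#' [mean_center()] exists to fix.
#'
#' @inheritParams simulate_perturbation_study
#' @param n_subjects number of subjects (default 10).
#' @param slope linear trend per unit x.
#' @param subject_offset_sd SD of per-subject random intercepts
#'   (default 0).
#' @return a `long_table` with a single category `"condition" = "all"`.
#' @export
simulate_trend <- function(n_subjects = 10, n_timepoints = 30, slope = 1,
                           noise_sd = 1, subject_offset_sd = 0,
                           x_range = c(0, 1), seed = NULL) {
  stopifnot(n_subjects >= 2, n_timepoints >= 2, noise_sd > 0,
            subject_offset_sd >= 0)
  with_seed(seed, {
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      b <- stats::rnorm(1, 0, subject_offset_sd)
      x <- jittered_times(n_timepoints, x_range[1], x_range[2])
      rows[[i]] <- data.frame(
        subject = sprintf("s_%02d", i),
        x = x,
        y = b + slope * x + stats::rnorm(n_timepoints, 0, noise_sd),
        condition = "all", stringsAsFactors = FALSE)
    }
    as_long_table(do.call(rbind, rows), "subject", "x", "y", "condition")
  })
}
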