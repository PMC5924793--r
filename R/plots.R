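save_if <- function(p, path, width, height) {
  if (!is.null(path)) ggplot2::ggsave(path, p, width = width, height = height)
  p
}

#' Observed spline(s) over translucent permuted splines
#'
#' For a two-group result, the two observed group splines are drawn in
#' color over the retained permuted spline pairs in translucent black. For
#' a trend result, the observed spline is drawn over the permuted splines
#' with the flat baseline as a dotted reference.
#'
#' @param result a `permuspliner_result` or `trendyspliner_result` with
#'   retained permuted curves (`retain_perm_curves > 0` at test time).
#' @param path optional image path; the format follows the extension
#'   (png/svg/pdf) via [ggplot2::ggsave()].
#' @param width,height saved image size in inches.
#' @return the ggplot object.
#' @export
plot_permsplines <- function(result, path = NULL, width = 7, height = 5) {
  if (inherits(result, "permuspliner_result")) {
    pc <- result$perm_curves
    if (is.null(pc)) {
      stop("no permuted curves retained; rerun with retain_perm_curves > 0")
    }
    perm_long <- rbind(
      data.frame(perm = pc$perm, x = pc$x, y = pc$y1, half = "a"),
      data.frame(perm = pc$perm, x = pc$x, y = pc$y2, half = "b")
    )
    obs <- rbind(
      data.frame(x = result$spline1$x, y = result$spline1$y,
                 group = result$groups[1]),
      data.frame(x = result$spline2$x, y = result$spline2$y,
                 group = result$groups[2])
    )
    p <- ggplot2::ggplot() +
      ggplot2::geom_line(
        data = perm_long,
        ggplot2::aes(x = x, y = y,
                     group = interaction(perm, half)),
        colour = "black", alpha = 0.08) +
      ggplot2::geom_line(
        data = obs,
        ggplot2::aes(x = x, y = y, colour = group),
        linewidth = 1) +
      ggplot2::labs(x = "x", y = "response", colour = result$category) +
      ggplot2::theme_bw()
  } else if (inherits(result, "trendyspliner_result")) {
    pc <- result$perm_curves
    if (is.null(pc)) {
      stop("no permuted curves retained; rerun with retain_perm_curves > 0")
    }
    obs <- data.frame(x = result$spline$x, y = result$spline$y)
    p <- ggplot2::ggplot() +
      ggplot2::geom_line(
        data = pc, ggplot2::aes(x = x, y = y, group = perm),
        colour = "black", alpha = 0.08) +
      ggplot2::geom_hline(yintercept = result$baseline_value,
                          linetype = "dotted") +
      ggplot2::geom_line(data = obs, ggplot2::aes(x = x, y = y),
                         colour = "red", linewidth = 1) +
      ggplot2::labs(x = "x", y = "response") +
      ggplot2::theme_bw()
  } else {
    stop("result must be a permuspliner_result or trendyspliner_result")
  }
  save_if(p, path, width, height)
}

#' Observed pointwise group distance over permuted distances
#'
#' Draws `|spline1 - spline2|` along the grid as a highlighted line over
#' the same quantity for each retained permuted spline pair in translucent
#' black: the visual counterpart of the overall area statistic.
#'
#' @inheritParams plot_permsplines
#' @param result a `permuspliner_result` with retained permuted curves.
#' @return the ggplot object.
#' @export
plot_distance <- function(result, path = NULL, width = 7, height = 5) {
  if (!inherits(result, "permuspliner_result")) {
    stop("result must be a permuspliner_result")
  }
  pc <- result$perm_curves
  if (is.null(pc)) {
    stop("no permuted curves retained; rerun with retain_perm_curves > 0")
  }
  perm_d <- data.frame(perm = pc$perm, x = pc$x, d = abs(pc$y1 - pc$y2))
  obs_d <- data.frame(x = result$spline1$x,
                      d = abs(result$spline1$y - result$spline2$y))
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = perm_d,
                       ggplot2::aes(x = x, y = d, group = perm),
                       colour = "black", alpha = 0.08) +
    ggplot2::geom_line(data = obs_d, ggplot2::aes(x = x, y = d),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "x", y = "|group 1 - group 2|") +
    ggplot2::theme_bw()
  save_if(p, path, width, height)
}

#' Interval-wise p-values along the time axis
#'
#' Scatter of p-value against x on a log-scaled p axis with a dotted
#' reference line at 0.05. Point area is proportional to the total number
#' of subjects contributing at that interval, so sparse boundary regions
#' read as small points. Gated intervals (too few subjects in either
#' group) are not drawn; if every interval is gated an annotated empty
#' plot is returned with a warning.
#'
#' @inheritParams plot_permsplines
#' @param result a `sliding_result`.
#' @return the ggplot object.
#' @export
plot_sliding_pvals <- function(result, path = NULL, width = 7, height = 5) {
  if (!inherits(result, "sliding_result")) {
    stop("result must be a sliding_result")
  }
  tab <- result$table
  pts <- tab[!is.na(tab$p_value), , drop = FALSE]
  if (nrow(pts) == 0) {
    warning("all intervals gated: no group reached test_density = ",
            result$params$test_density)
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0.5, y = 0.5,
                        label = "no intervals met test_density") +
      ggplot2::theme_void()
    return(save_if(p, path, width, height))
  }
  pts$n_total <- pts$n_group1 + pts$n_group2
  p <- ggplot2::ggplot(pts,
                       ggplot2::aes(x = x, y = p_value, size = n_total)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(name = "subjects") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dotted") +
    ggplot2::labs(x = "x", y = "p-value") +
    ggplot2::theme_bw()
  save_if(p, path, width, height)
}
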