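#' Fit a local polynomial (loess) smoother
#'
#' The smoothing primitive shared by all tests in the package. Fitting only
#' validates and stores the data (sorted by x); all estimation happens
#' pointwise at prediction time, so two models fit on the same data always
#' predict identically regardless of input order.
#'
#' @param x,y numeric vectors of equal length; all values finite.
#' @param span fraction of the data in each local neighborhood, in (0, 1].
#'   Larger span means a smoother curve.
#' @param degree local polynomial degree, 1 or 2.
#' @return a `loess_model` with elements `x`, `y` (sorted by x), `span`,
#'   `degree`, `x_min`, `x_max`, `n`.
#' @seealso [predict_loess()]
#' @examples
#' m <- fit_loess(1:10, (1:10) * 2 + 1)
#' predict_loess(m, c(2.5, 7.25))
#' @export
fit_loess <- function(x, y, span = 0.75, degree = 2) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in x or y")
  }
  if (!(length(span) == 1 && is.finite(span) && span > 0 && span <= 1)) {
    stop("span must be a single value in (0, 1]")
  }
  degree <- as.integer(degree)
  if (!(length(degree) == 1 && degree %in% c(1L, 2L))) {
    stop("degree must be 1 or 2")
  }
  ndx <- length(unique(x))
  if (ndx < degree + 2L) {
    stop("insufficient data: a degree-", degree, " local fit needs at least ",
         degree + 2L, " distinct x values (got ", ndx, ")")
  }
  o <- order(x)
  x <- x[o]
  y <- y[o]
  structure(list(x = x, y = y, span = span, degree = degree,
                 x_min = x[1L], x_max = x[length(x)], n = length(x)),
            class = "loess_model")
}

#' Predict from a loess model, without extrapolation
#'
#' For each query point inside the fitted range, the `ceil(span * n)`
#' nearest training points (clamped to at least `degree + 2`, ties at the
#' cutoff distance all included) are weighted by the tricube kernel
#' `(1 - (d/dmax)^3)^3` and a weighted least-squares polynomial centered at
#' the query point is solved; its intercept is the prediction. Query points
#' outside `[x_min, x_max]` return `NA` — the curve is never extrapolated
#' beyond the observed range. A singular local system falls back to a
#' lower degree, then to the weighted mean.
#'
#' @param model a `loess_model` from [fit_loess()].
#' @param x_new numeric vector of query points.
#' @return numeric vector of predictions, `NA` outside the fitted range.
#' @export
predict_loess <- function(model, x_new) {
  stopifnot(inherits(model, "loess_model"))
  loess_predict_cpp(model$x, model$y, as.numeric(x_new),
                    model$span, model$degree)
}

#' @rdname predict_loess
#' @param object a `loess_model`.
#' @param newdata numeric vector of query points.
#' @param ... unused.
#' @export
predict.loess_model <- function(object, newdata, ...) {
  predict_loess(object, newdata)
}

#' @export
print.loess_model <- function(x, ...) {
  cat("loess model: n =", x$n, ", span =", x$span, ", degree =", x$degree,
      ", range [", x$x_min, ",", x$x_max, "]\n")
  invisible(x)
}
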