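#' Empirical p-value with add-one smoothing
#'
#' `p = (b + 1) / (m + 1)` where `b` counts permuted statistics at least as
#' extreme as the observed one (`>=` for `direction = "more"`, `<=` for
#' `"less"`; ties count against the alternative). The attainable floor is
#' `1/(m + 1)`: 0.001 at the default 999 permutations.
#'
#' @param observed the observed statistic.
#' @param permuted numeric vector of permuted statistics.
#' @param direction `"more"` tests for a statistic larger than chance,
#'   `"less"` for smaller.
#' @return the empirical p-value, in `[1/(m+1), 1]`.
#' @export
empirical_p <- function(observed, permuted, direction = c("more", "less")) {
  direction <- match.arg(direction)
  if (length(permuted) < 1) stop("permuted vector is empty")
  if (!is.finite(observed)) stop("observed statistic is not finite")
  m <- length(permuted)
  b <- if (direction == "more") sum(permuted >= observed)
       else sum(permuted <= observed)
  (b + 1) / (m + 1)
}

#' Shuffle subject-level group labels
#'
#' Permutes which subject carries which label, preserving the multiset of
#' labels (group sizes never change). Each subject keeps all of its
#' observations; only the label moves. Uses the current RNG stream.
#'
#' @param labels named character vector: subject id -> group label, with
#'   exactly two distinct labels.
#' @return the same named vector with the labels randomly reassigned.
#' @export
permute_group_labels <- function(labels) {
  if (length(labels) < 2) stop("need at least 2 subjects")
  if (length(unique(labels)) != 2) {
    stop("exactly 2 distinct group labels required")
  }
  out <- labels
  out[] <- sample(unname(labels))
  out
}

#' Permute responses across time within each subject
#'
#' For each subject independently, the multiset of that subject's y values
#' is randomly reassigned across that subject's own x positions. x values
#' and subject membership never change; across-subject structure is
#' untouched. Uses the current RNG stream.
#'
#' @param tbl a `long_table`.
#' @return the table with y permuted within subjects.
#' @export
permute_within_subject <- function(tbl) {
  idx <- split(seq_len(nrow(tbl)), tbl$subject)
  y <- tbl$y
  for (ii in idx) {
    if (length(ii) > 1) y[ii] <- y[ii][sample.int(length(ii))]
  }
  tbl$y <- y
  tbl
}
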