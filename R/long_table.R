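#' Coerce a data frame to a validated long-format longitudinal table
#'
#' The universal input of the package: one row per observation, with a
#' subject identifier, a numeric independent axis (time or any continuous
#' axis), a numeric response, and zero or more categorical metadata columns.
#' Rows with a missing subject or a non-finite x or y are dropped and
#' counted; category values and subject ids are compared as exact strings
#' after trimming surrounding whitespace.
#'
#' @param data a data.frame in long format.
#' @param subject_col,x_col,y_col names of the subject, independent-axis,
#'   and response columns in `data`.
#' @param category_cols character vector of categorical metadata columns to
#'   carry along (may be `NULL`).
#' @param quiet suppress the message reporting dropped rows.
#' @return a `long_table`: a data.frame with canonical columns `subject`
#'   (character), `x`, `y` (numeric) plus the requested category columns,
#'   with attribute `dropped_rows` giving the number of rows removed.
#' @examples
#' df <- data.frame(id = c("a", "a", "b", "b"), day = 1:4,
#'                  abund = c(0.1, 0.2, 0.4, 0.3), abx = "no")
#' as_long_table(df, "id", "day", "abund", "abx")
#' @export
as_long_table <- function(data, subject_col = "subject", x_col = "x",
                          y_col = "y", category_cols = NULL, quiet = TRUE) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  need <- unique(c(subject_col, x_col, y_col, category_cols))
  absent <- setdiff(need, names(data))
  if (length(absent) > 0) {
    stop("column(s) not found: ", paste(absent, collapse = ", "),
         "; available columns: ", paste(names(data), collapse = ", "))
  }
  out <- data.frame(
    subject = trimws(as.character(data[[subject_col]])),
    x = suppressWarnings(as.numeric(as.character(data[[x_col]]))),
    y = suppressWarnings(as.numeric(as.character(data[[y_col]]))),
    stringsAsFactors = FALSE
  )
  for (cc in category_cols) out[[cc]] <- trimws(as.character(data[[cc]]))
  bad <- is.na(out$subject) | out$subject == "" |
    !is.finite(out$x) | !is.finite(out$y)
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no valid rows remain after dropping incomplete observations")
  }
  if (length(unique(out$subject)) < 2) {
    stop("need at least 2 distinct subjects")
  }
  if (length(unique(out$x)) < 2) {
    stop("need at least 2 distinct x values")
  }
  rownames(out) <- NULL
  if (!quiet && n_dropped > 0) {
    message(n_dropped, " row(s) dropped (missing subject, x, or y)")
  }
  structure(out, class = c("long_table", "data.frame"),
            categories = as.character(category_cols %||% character()),
            dropped_rows = n_dropped)
}

#' Read a long-format longitudinal table from a delimited text file
#'
#' Reads a tab-delimited file with a single header row (a comma-delimited
#' dialect is auto-detected by sniffing the header line) and validates it
#' with [as_long_table()].
#'
#' @inheritParams as_long_table
#' @param path path to the input file.
#' @return a `long_table` (see [as_long_table()]).
#' @export
read_long_table <- function(path, subject_col, x_col, y_col,
                            category_cols = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t"
         else if (grepl(",", header, fixed = TRUE)) ","
         else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  as_long_table(raw, subject_col, x_col, y_col, category_cols, quiet = quiet)
}

#' Write a long table to tab-delimited text
#'
#' @param tbl a `long_table`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(tbl, path, sep = "\t") {
  utils::write.table(tbl, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop low-prevalence subjects
#'
#' Retains exactly the subjects having strictly more than `cut_low`
#' observations, so `cut_low = 1` removes subjects appearing only once and
#' `cut_low = 0` keeps everyone. The strict inequality is a deliberate
#' reading of the threshold; it is documented here and in the CLI help.
#'
#' @param tbl a `long_table`.
#' @param cut_low non-negative integer threshold.
#' @return the filtered `long_table`, with attribute `dropped_subjects`.
#' @export
filter_low_prevalence <- function(tbl, cut_low) {
  stopifnot(is.numeric(cut_low), length(cut_low) == 1, cut_low >= 0)
  counts <- table(tbl$subject)
  keep <- names(counts)[counts > cut_low]
  if (length(keep) == 0) {
    stop("all subjects removed by cut_low = ", cut_low)
  }
  dropped <- setdiff(names(counts), keep)
  out <- tbl[tbl$subject %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("long_table", "data.frame"),
            categories = attr(tbl, "categories"),
            dropped_subjects = dropped)
}

#' Split a long table into two comparison groups
#'
#' Rows whose category value equals neither label are excluded. Every
#' subject must carry a single label across all of its rows; a subject with
#' conflicting labels is an error (it cannot be permuted as a unit).
#'
#' @param tbl a `long_table`.
#' @param category name of the category column.
#' @param group1,group2 the two labels to compare.
#' @return a `group_pair`: list with `group1_table`, `group2_table`,
#'   `category`, `group1`, `group2`.
#' @export
split_groups <- function(tbl, category, group1, group2) {
  if (!category %in% names(tbl)) {
    stop("category column '", category, "' not found; available: ",
         paste(names(tbl), collapse = ", "))
  }
  vals <- trimws(as.character(tbl[[category]]))
  g1 <- trimws(group1)
  g2 <- trimws(group2)
  if (identical(g1, g2)) stop("group1 and group2 must differ")
  for (g in c(g1, g2)) {
    if (!any(vals == g)) {
      stop("group label '", g, "' not present in category '", category, "'")
    }
  }
  keep <- vals %in% c(g1, g2)
  sub <- tbl[keep, , drop = FALSE]
  lab <- vals[keep]
  nlab <- tapply(lab, sub$subject, function(v) length(unique(v)))
  if (any(nlab > 1)) {
    stop("subject(s) with inconsistent group labels: ",
         paste(names(nlab)[nlab > 1], collapse = ", "))
  }
  t1 <- sub[lab == g1, , drop = FALSE]
  t2 <- sub[lab == g2, , drop = FALSE]
  rownames(t1) <- NULL
  rownames(t2) <- NULL
  cls <- c("long_table", "data.frame")
  structure(list(group1_table = structure(t1, class = cls,
                                          categories = attr(tbl, "categories")),
                 group2_table = structure(t2, class = cls,
                                          categories = attr(tbl, "categories")),
                 category = category, group1 = g1, group2 = g2),
            class = "group_pair")
}
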