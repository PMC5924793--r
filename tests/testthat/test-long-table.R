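test_that("read_long_table parses a TSV, attaches categories, drops bad rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("subject\tmonth\tabundance\tabx",
               "s1\t1\t0.1\tyes",
               "s1\t2\t0.2\tyes",
               "s2\t1\t0.3\tno",
               "s2\t2\t0.4\tno"), path)
  tbl <- read_long_table(path, "subject", "month", "abundance", "abx",
                         quiet = TRUE)
  expect_s3_class(tbl, "long_table")
  expect_equal(nrow(tbl), 4)
  expect_named(tbl, c("subject", "x", "y", "abx"))
  expect_equal(attr(tbl, "dropped_rows"), 0)

  # a y of "NA" is dropped and counted
  writeLines(c("subject\tmonth\tabundance\tabx",
               "s1\t1\t0.1\tyes",
               "s1\t2\tNA\tyes",
               "s2\t1\t0.3\tno",
               "s2\t2\t0.4\tno"), path)
  tbl2 <- read_long_table(path, "subject", "month", "abundance", "abx",
                          quiet = TRUE)
  expect_equal(nrow(tbl2), 3)
  expect_equal(attr(tbl2, "dropped_rows"), 1)

  # schema error lists available columns
  expect_error(
    read_long_table(path, "subject", "day", "abundance", quiet = TRUE),
    "day.*available", ignore.case = TRUE)
  expect_error(read_long_table(file.path(tempdir(), "nope.tsv"),
                               "s", "x", "y"), "not found")
})

test_that("comma-delimited dialect is auto-detected from the header", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("subject,month,abundance",
               "s1,1,0.1", "s1,2,0.2", "s2,1,0.3", "s2,2,0.4"), path)
  tbl <- read_long_table(path, "subject", "month", "abundance", quiet = TRUE)
  expect_equal(tbl$y, c(0.1, 0.2, 0.3, 0.4))
})

test_that("read -> write -> read round-trips the table", {
  tbl <- simulate_null(n_per_group = 3, n_timepoints = 4, seed = 7)
  tbl$x <- round(tbl$x, 6)
  tbl$y <- round(tbl$y, 6)
  path <- tempfile(fileext = ".tsv")
  write_long_table(tbl, path)
  back <- read_long_table(path, "subject", "x", "y", "condition",
                          quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("filter_low_prevalence keeps subjects with count > cut_low", {
  df <- data.frame(
    subject = rep(c("a", "b", "c"), times = c(5, 3, 1)),
    x = c(1:5, 1:3, 1), y = 0, grp = "g")
  tbl <- as_long_table(df, "subject", "x", "y", "grp")
  f1 <- filter_low_prevalence(tbl, 1)
  expect_setequal(unique(f1$subject), c("a", "b"))
  expect_equal(attr(f1, "dropped_subjects"), "c")

  # cut_low = 0 keeps everything
  f0 <- filter_low_prevalence(tbl, 0)
  expect_equal(as.data.frame(f0), as.data.frame(tbl), ignore_attr = TRUE)

  # removing everyone is an error naming the threshold
  df2 <- data.frame(subject = rep(c("a", "b"), each = 2),
                    x = c(1, 2, 1, 2), y = 0)
  tbl2 <- as_long_table(df2, "subject", "x", "y")
  expect_error(filter_low_prevalence(tbl2, 2), "cut_low = 2")

  # idempotence
  expect_equal(as.data.frame(filter_low_prevalence(f1, 1)),
               as.data.frame(f1), ignore_attr = TRUE)
})

test_that("split_groups excludes other labels and rejects conflicts", {
  df <- data.frame(
    subject = c("s1", "s1", "s2", "s2", "s3", "s3"),
    x = rep(1:2, 3), y = rnorm(6),
    abx = c("yes", "yes", "no", "no", "unknown", "unknown"))
  tbl <- as_long_table(df, "subject", "x", "y", "abx")
  pair <- split_groups(tbl, "abx", "yes", "no")
  expect_equal(unique(pair$group1_table$subject), "s1")
  expect_equal(unique(pair$group2_table$subject), "s2")
  # union of the two groups == input restricted to the two labels
  expect_equal(nrow(pair$group1_table) + nrow(pair$group2_table),
               sum(df$abx %in% c("yes", "no")))

  # subject with conflicting labels is rejected by name
  df$abx[2] <- "no"
  tbl2 <- as_long_table(df, "subject", "x", "y", "abx")
  expect_error(split_groups(tbl2, "abx", "yes", "no"), "s1")

  # absent label
  expect_error(split_groups(tbl, "abx", "yes", "maybe"), "maybe")
})

test_that("split_groups yields disjoint subject sets on clean groups", {
  tbl <- make_two_group_table(n_per_group = 5)
  pair <- split_groups(tbl, "grp", "g1", "g2")
  s1 <- unique(pair$group1_table$subject)
  s2 <- unique(pair$group2_table$subject)
  expect_length(s1, 5)
  expect_length(s2, 5)
  expect_length(intersect(s1, s2), 0)
})

test_that("validation rejects degenerate tables and trims whitespace", {
  expect_error(as_long_table(data.frame(subject = "a", x = 1, y = 1)),
               "2 distinct subjects")
  expect_error(
    as_long_table(data.frame(subject = c("a", "b"), x = 1, y = 1)),
    "2 distinct x")
  df <- data.frame(subject = c(" a ", "a", "b", "b"),
                   x = c(1, 2, 1, 2), y = 1:4, g = c("u ", " u", "v", "v"))
  tbl <- as_long_table(df, "subject", "x", "y", "g")
  expect_equal(unique(tbl$subject), c("a", "b"))
  expect_setequal(unique(tbl$g), c("u", "v"))
  # all rows invalid -> empty-input error
  expect_error(
    as_long_table(data.frame(subject = c("a", "b"),
                             x = c(NA, NA), y = 1:2)),
    "no valid rows")
})
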