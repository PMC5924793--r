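test_that("group_distance sums absolute pointwise differences", {
  expect_equal(group_distance(rep(2, 10), rep(2, 10)), 0)
  expect_equal(group_distance(rep(3, 1000), rep(1.5, 1000)), 1500)
  # y = x vs y = x^2 on {0, 0.5, 1}: |0| + |0.25| + |0| = 0.25
  g <- c(0, 0.5, 1)
  expect_equal(group_distance(g, g^2), 0.25)
  # pairwise exclusion of missing grid points
  expect_equal(group_distance(c(1, NA, 3, 4), c(0, 5, NA, 1)), 4)
  expect_error(group_distance(c(1, NA), c(NA, 1)), "2 shared")
  expect_error(group_distance(1:3, 1:4), "same grid")
})

test_that("permute_group_labels conserves the label multiset and is uniform", {
  labels <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  set.seed(1)
  p <- permute_group_labels(labels)
  expect_equal(sort(unname(p)), c("A", "A", "B", "B"))
  expect_named(p, names(labels))

  # uniformity over the choose(4,2) = 6 assignments
  set.seed(2)
  draws <- replicate(3000, paste(permute_group_labels(labels),
                                 collapse = ""))
  counts <- table(draws)
  expect_length(counts, 6)
  expect_gt(chisq.test(counts)$p.value, 0.001)

  # determinism under a fixed seed
  set.seed(10); a <- replicate(5, permute_group_labels(labels))
  set.seed(10); b <- replicate(5, permute_group_labels(labels))
  expect_identical(a, b)

  expect_error(permute_group_labels(c(s1 = "A")), "2 subjects")
  expect_error(permute_group_labels(c(s1 = "A", s2 = "A")), "2 distinct")
})

test_that("empirical_p implements add-one smoothing in both directions", {
  # 2 of 999 permuted values >= observed -> 3/1000
  perm <- c(rep(1, 997), 5, 6)
  expect_equal(empirical_p(4, perm, "more"), 0.003)
  # observed beyond all permuted values -> the floor 1/1000
  expect_equal(empirical_p(10, rep(1, 999), "more"), 0.001)
  # observed below all permuted values, direction more -> 1
  expect_equal(empirical_p(0, rep(1, 999), "more"), 1.0)
  # less direction mirrors
  expect_equal(empirical_p(0, rep(1, 999), "less"), 0.001)
  # ties count against the alternative (inclusive comparison)
  expect_equal(empirical_p(1, c(1, 2, 3), "more"), 1.0)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("permuspliner is reproducible and direction-complementary", {
  tbl <- simulate_perturbation_study(n_per_group = 5, n_timepoints = 10,
                                     magnitude = 2, seed = 5)
  r1 <- permuspliner(tbl, category = "condition", perms = 49, ints = 60,
                     seed = 99)
  r2 <- permuspliner(tbl, category = "condition", perms = 49, ints = 60,
                     seed = 99)
  expect_identical(r1$permuted_distances, r2$permuted_distances)
  expect_identical(r1$p_value, r2$p_value)

  # p stays within [1/(m+1), 1]
  expect_gte(r1$p_value, 1 / 50)
  expect_lte(r1$p_value, 1)

  # more/less complementarity up to add-one smoothing on the same draws
  rl <- permuspliner(tbl, category = "condition", perms = 49, ints = 60,
                     test_direction = "less", seed = 99)
  expect_identical(rl$permuted_distances, r1$permuted_distances)
  b_more <- sum(r1$permuted_distances >= r1$observed_distance)
  b_less <- sum(rl$permuted_distances <= rl$observed_distance)
  expect_gte(b_more + b_less, 49)  # every draw counted at least once
  expect_equal(rl$p_value, (b_less + 1) / 50)
})

test_that("swapping the group labels leaves distance and p unchanged", {
  tbl <- simulate_perturbation_study(n_per_group = 5, n_timepoints = 8,
                                     magnitude = 1, seed = 21)
  a <- permuspliner(tbl, category = "condition", group1 = "control",
                    group2 = "perturbed", perms = 59, ints = 50, seed = 7)
  b <- permuspliner(tbl, category = "condition", group1 = "perturbed",
                    group2 = "control", perms = 59, ints = 50, seed = 7)
  expect_equal(a$observed_distance, b$observed_distance)
  expect_identical(a$permuted_distances, b$permuted_distances)
  expect_identical(a$p_value, b$p_value)
})

test_that("permuspliner enforces sparsity and overlap requirements", {
  tbl <- make_two_group_table(n_per_group = 2, n_time = 3)
  expect_error(
    permuspliner(tbl, category = "grp", perms = 9, cut_sparse = 10),
    "cut_sparse")
  expect_error(
    permuspliner(tbl, category = "grp", perms = 9, cut_sparse = 2),
    "cut_sparse must be at least 4")

  # disjoint x ranges between groups -> no overlap
  df <- rbind(
    data.frame(subject = rep(c("a1", "a2"), each = 5),
               x = rep(1:5, 2), y = rnorm(10), g = "a"),
    data.frame(subject = rep(c("b1", "b2"), each = 5),
               x = rep(11:15, 2), y = rnorm(10), g = "b"))
  expect_error(
    permuspliner(df, category = "g", group1 = "a", group2 = "b",
                 perms = 9, ints = 20),
    "overlap")
})

test_that("retained permuted curves respect the retention cap", {
  tbl <- make_two_group_table(n_per_group = 3, n_time = 6)
  res <- permuspliner(tbl, category = "grp", perms = 19, ints = 30,
                      seed = 1, retain_perm_curves = 5)
  expect_equal(length(unique(res$perm_curves$perm)), 5)
  res0 <- permuspliner(tbl, category = "grp", perms = 9, ints = 30,
                       seed = 1, retain_perm_curves = 0)
  expect_null(res0$perm_curves)
})
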