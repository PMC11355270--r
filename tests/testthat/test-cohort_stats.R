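test_that("spherical equivalent follows sphere + cylinder/2", {
  expect_equal(spherical_equivalent(0, 0), 0)
  expect_equal(spherical_equivalent(-2.0, -1.0), -2.5)
  expect_equal(spherical_equivalent(1.0, -0.5), 0.75)
})

test_that("exclusion rules drop low-signal and flagged scans with reasons", {
  records <- data.frame(eye_id = c("a", "b", "c", "d"),
                        signal_strength = c(5, 6, 9, 10))
  flags <- data.frame(eye_id = c("c", "d"),
                      motion = c(TRUE, FALSE),
                      floater = c(FALSE, FALSE))
  res <- apply_exclusions(records, flags)
  expect_setequal(res$kept$eye_id, c("b", "d"))
  expect_equal(res$excluded$reason[res$excluded$eye_id == "a"], "signal_strength")
  expect_equal(res$excluded$reason[res$excluded$eye_id == "c"], "motion")
})

test_that("random eye selection is seeded, fair, and keeps singletons", {
  one <- data.frame(participant_id = "p1", eye_id = "p1_OD")
  expect_equal(select_random_eye(one, seed = 3)$selected$eye_id, "p1_OD")
  two <- data.frame(participant_id = rep(sprintf("p%04d", 1:1000), each = 2),
                    eye_id = paste0(rep(sprintf("p%04d", 1:1000), each = 2),
                                    c("_OD", "_OS")))
  s1 <- select_random_eye(two, seed = 11)
  s2 <- select_random_eye(two, seed = 11)
  expect_identical(s1$selected, s2$selected)
  frac_od <- mean(grepl("_OD$", s1$selected$eye_id))
  expect_gt(frac_od, 0.45); expect_lt(frac_od, 0.55)
  # participant with zero eligible eyes (factor level without rows) is dropped
  lvls <- factor(two$participant_id, levels = c(unique(two$participant_id), "p_gone"))
  two$participant_id <- lvls
  expect_equal(select_random_eye(two, seed = 1)$dropped, "p_gone")
})

test_that("pooled t from summaries reproduces published group comparisons", {
  al <- t_test_from_summary(group_summary(24.7, 1.5, 92),
                            group_summary(23.2, 0.9, 99))
  expect_lt(al$p_value, 0.001)
  expect_equal(al$df, 189)
  scp <- t_test_from_summary(group_summary(42.4, 2.6, 92),
                             group_summary(40.9, 2.5, 99))
  expect_equal(scp$statistic, 4.06, tolerance = 0.01)
  expect_lt(scp$p_value, 0.001)
  same <- t_test_from_summary(group_summary(5, 1, 10), group_summary(5, 1, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary-path t equals the raw-data path and stats::t.test", {
  set.seed(21)
  x <- rnorm(40, 10, 2); y <- rnorm(55, 9, 2.5)
  via_summary <- t_test_from_summary(
    group_summary(mean(x), sd(x), length(x)),
    group_summary(mean(y), sd(y), length(y)))
  via_raw <- t_test_from_summary(x, y)
  expect_equal(via_raw$statistic, via_summary$statistic, tolerance = 1e-12)
  expect_equal(via_raw$p_value, via_summary$p_value, tolerance = 1e-12)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(via_raw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(via_raw$p_value, ref$p.value, tolerance = 1e-12)
  refw <- stats::t.test(x, y)
  ww <- t_test_from_summary(x, y, welch = TRUE)
  expect_equal(ww$p_value, refw$p.value, tolerance = 1e-12)
  # antisymmetry in group order
  flip <- t_test_from_summary(y, x)
  expect_equal(flip$statistic, -via_raw$statistic, tolerance = 1e-12)
  expect_equal(flip$p_value, via_raw$p_value, tolerance = 1e-12)
})

test_that("2x2 chi-square matches published cohort characteristics", {
  sex <- chi_square_2x2(63, 29, 63, 36)
  expect_equal(round(sex$p_value, 3), 0.480)
  dm <- chi_square_2x2(0, 92, 2, 97)
  expect_equal(round(dm$p_value, 3), 0.171)
  htn <- chi_square_2x2(17, 75, 11, 88)
  expect_equal(round(htn$p_value, 3), 0.150)
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # invariances: transpose and column swap
  expect_equal(chi_square_2x2(63, 63, 29, 36)$p_value, sex$p_value)
  expect_equal(chi_square_2x2(29, 63, 36, 63)$p_value, sex$p_value)
  expect_error(chi_square_2x2(0, 0, 2, 97), "zero margin")
})

test_that("OLS adjustment recovers a planted effect and reduces to the mean difference", {
  set.seed(31)
  n <- 200
  tab <- data.frame(group = rep(0:1, each = n / 2),
                    age = rnorm(n, 45, 12), iop = rnorm(n, 16, 3))
  tab$y <- 2.0 * tab$group + 0.05 * tab$age - 0.1 * tab$iop + rnorm(n)
  fit <- adjusted_group_difference(tab, "y", "group", c("age", "iop"))
  se <- abs(fit$estimate / fit$statistic)
  expect_lt(abs(fit$estimate - 2.0), 3 * se)
  expect_equal(fit$df, n - 4)
  # without covariates the coefficient is the raw mean difference
  plain <- adjusted_group_difference(tab, "y", "group")
  expect_equal(plain$estimate,
               mean(tab$y[tab$group == 1]) - mean(tab$y[tab$group == 0]),
               tolerance = 1e-9)
  tab$flat <- 1
  expect_error(adjusted_group_difference(tab, "y", "group", "flat"),
               "singular")
  expect_error(adjusted_group_difference(tab, "y", "group", "nope"),
               "missing columns")
})

test_that("null OLS rejections stay near the nominal rate", {
  set.seed(41)
  hits <- 0L
  reps <- 400L
  for (r in seq_len(reps)) {
    n <- 80
    tab <- data.frame(group = rep(0:1, each = n / 2), x = rnorm(n))
    tab$y <- 0.3 * tab$x + rnorm(n)
    fit <- adjusted_group_difference(tab, "y", "group", "x")
    if (fit$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("comparison tables reproduce generator group structure", {
  cohort <- generate_cohort(cohort_recipe(seed = 77L))
  tabs <- build_comparison_tables(cohort)
  expect_equal(nrow(tabs$octa_metrics), 13L)
  expect_true(all(tabs$octa_metrics$method == "ols_coefficient"))
  # group means track the generating parameters (z-scores against SEM)
  rec <- cohort_recipe()
  z <- sapply(seq_len(13), function(i) {
    v <- rec$continuous[[tabs$octa_metrics$variable[i]]]
    # groups are ordered alphabetically: Caucasian = g1, Chinese = g2
    z1 <- (tabs$octa_metrics$mean_g1[i] - v[3]) / (v[4] / sqrt(rec$n[2]))
    z2 <- (tabs$octa_metrics$mean_g2[i] - v[1]) / (v[2] / sqrt(rec$n[1]))
    max(abs(z1), abs(z2))
  })
  expect_lt(max(z), 3.5)
  expect_gt(mean(z < 2), 0.8)
  # characteristics table carries both test families
  expect_true(any(tabs$characteristics$method == "chi_square"))
  expect_true(any(tabs$characteristics$method == "pooled_t"))
  # a zero-effect cohort should mostly not reject
  null_cohort <- generate_cohort(cohort_recipe(null_effect = TRUE, seed = 78L))
  null_tabs <- build_comparison_tables(null_cohort)
  pvals <- c(null_tabs$characteristics$p_value, null_tabs$octa_metrics$p_value)
  expect_gte(mean(pvals > 0.05, na.rm = TRUE), 0.8)
  single <- cohort[cohort$ethnicity == "Chinese", ]
  expect_error(build_comparison_tables(single), "two groups")
})
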