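test_that("ANOVA with Tukey handles identical, separated and permuted groups", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_tukey(same)
  expect_equal(res$omnibus$statistic, 0)
  expect_equal(res$omnibus$p_raw, 1)
  # all values identical everywhere: degenerate zero-variance case
  flat <- anova_tukey(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(flat$omnibus$statistic, 0)
  expect_equal(flat$omnibus$p_raw, 1)
  expect_true(all(flat$pairwise$p_adjusted == 1))
  # two groups ten SDs apart at n = 50
  set.seed(1)
  far <- list(a = rnorm(50, 0, 1), b = rnorm(50, 10, 1))
  res_far <- anova_tukey(far)
  expect_lt(res_far$pairwise$p_adjusted[1], 1e-6)
  expect_true(res_far$pairwise$significant[1])
  # omnibus is invariant to group order
  set.seed(2)
  g <- list(a = rnorm(20), b = rnorm(20, 1), c = rnorm(20, 2))
  expect_equal(anova_tukey(g)$omnibus$statistic,
               anova_tukey(rev(g))$omnibus$statistic)
})

test_that("pairwise chi-squared matches hand-computed Pearson statistics", {
  even <- matrix(c(50, 50, 50, 50), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("success", "failure")))
  res <- pairwise_chi2(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  # [[90,10],[10,90]]: all expected cells 50, chi2 = 4 * 40^2 / 50 = 128
  skewed <- matrix(c(90, 10, 10, 90), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("success", "failure")))
  expect_equal(pairwise_chi2(skewed)$statistic, 128)
  # row swap leaves the statistic unchanged
  swapped <- skewed[c(2, 1), ]
  expect_equal(pairwise_chi2(swapped)$statistic, 128)
  # zero margin -> not applicable, reported as NA
  degenerate <- matrix(c(0, 0, 10, 90), nrow = 2, byrow = TRUE,
                       dimnames = list(c("a", "b"), c("success", "failure")))
  expect_true(is.na(pairwise_chi2(degenerate)$statistic))
  # three groups -> three adjusted pairwise tests
  three <- matrix(c(90, 10, 80, 20, 50, 50), nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("s", "f")))
  res3 <- pairwise_chi2(three)
  expect_equal(nrow(res3), 3L)
  expect_true(all(res3$p_adjusted >= res3$p_raw))
})

test_that("Kruskal-Wallis with Dunn behaves on degenerate and shifted groups", {
  same <- list(a = rep(1, 5), b = rep(1, 5))
  res <- kruskal_dunn(same)
  expect_equal(res$omnibus$statistic, 0)
  expect_equal(res$omnibus$p_raw, 1)
  expect_equal(res$pairwise$p_raw, 1)
  set.seed(3)
  shifted <- list(a = rnorm(100), b = rnorm(100) + 50)
  res_s <- kruskal_dunn(shifted)
  expect_lt(res_s$pairwise$p_adjusted[1], 1e-4)
  # rank invariance under monotone transforms
  g <- list(a = rexp(30), b = rexp(30) * 2)
  expect_equal(kruskal_dunn(g)$omnibus$statistic,
               kruskal_dunn(lapply(g, log))$omnibus$statistic)
})

test_that("Dunn z agrees with the Kruskal-Wallis H identity for two groups", {
  # for k = 2 the tie-corrected Dunn z satisfies z^2 = H, with or
  # without ties; this pins the hand-written variance term to kruskal.test
  set.seed(4)
  no_ties <- list(a = rnorm(15), b = rnorm(12, 0.5))
  with_ties <- list(a = sample(1:4, 20, TRUE), b = sample(2:6, 25, TRUE))
  for (g in list(no_ties, with_ties)) {
    h <- kruskal_dunn(g)$omnibus$statistic
    z <- dunn_test(g)$statistic
    expect_equal(z^2, h, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg adjustment reproduces the step-up worked example", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.2, 4)), rep(0.2, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted never below raw, for every exposed method
  set.seed(5)
  p <- runif(20)
  for (m in c("bh", "holm", "bonferroni"))
    expect_true(all(adjust_pvalues(p, m) >= p))
})

test_that("the full analysis populates every report section", {
  tab <- simulate_study("expert", study_config(), seed = 71)
  fit <- analyze_study(tab)
  expect_s3_class(fit, "layout_study")
  expect_equal(sort(names(fit$learning_curves)),
               c("circular", "half_matrix", "matrix"))
  for (lc in fit$learning_curves) expect_equal(nrow(lc), 15L)
  expect_equal(nrow(fit$consistency_test$pairwise), 3L)
  expect_equal(nrow(fit$accuracy_test), 3L)
  expect_equal(nrow(fit$rt_test$pairwise), 3L)
  expect_equal(nrow(fit$min_distance_test$pairwise), 3L)
  expect_equal(nrow(fit$breakdown$class_fractions), 3L)
  # significance flags are recomputable from adjusted p and alpha
  for (tr in list(fit$accuracy_test, fit$rt_test$pairwise,
                  fit$min_distance_test$pairwise)) {
    expect_equal(tr$significant,
                 !is.na(tr$p_adjusted) & tr$p_adjusted < 0.05)
    expect_true(all(is.na(tr$p_raw) | tr$p_adjusted >= tr$p_raw - 1e-12))
  }
  expect_output(print(fit), "Layout perception study analysis")
  expect_output(summary(fit), "Error breakdown")
})

test_that("analysis is deterministic given the table", {
  tab <- simulate_study("expert", study_config(), seed = 72)
  f1 <- analyze_study(tab)
  f2 <- analyze_study(tab)
  f1$responses <- f2$responses <- NULL  # aov keeps environments; compare results
  expect_equal(f1$consistency_test$omnibus, f2$consistency_test$omnibus)
  expect_equal(f1$accuracy_test, f2$accuracy_test)
  expect_equal(f1$min_distance_test, f2$min_distance_test)
})

test_that("clearly different accuracies are detected, at study scale", {
  cfg <- study_config()
  hi <- participant_profile(p_correct = 0.95, memory = 0.8)
  lo <- participant_profile(p_correct = 0.75, memory = 0.8)
  tab <- simulate_study(list(cohort_spec("circular", 50, hi),
                             cohort_spec("matrix", 50, lo)), cfg, seed = 73)
  fit <- analyze_study(tab)
  expect_true(all(fit$accuracy_test$significant))
})
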