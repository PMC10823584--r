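test_that("ROC AUC matches hand enumeration and closed cases", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 3 / 4)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  # ties count one half
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC and pAUC agree with an independent reference implementation", {
  set.seed(81)
  for (i in 1:10) {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- rnorm(n, mean = y)
    r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    expect_equal(roc_auc(y, s), as.numeric(pROC::auc(r)), tolerance = 1e-10)
    want <- as.numeric(pROC::auc(r, partial.auc = c(1, 0.9),
                                 partial.auc.focus = "specificity",
                                 partial.auc.correct = FALSE))
    expect_equal(pauc01(y, s, normalised = FALSE), want, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(82)
  y <- rbinom(100, 1, 0.25)
  s <- rnorm(100, mean = y)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 1 / (1 + exp(-3 * s))), a)
  expect_equal(pauc01(y, s), pauc01(y, exp(s)), tolerance = 1e-12)
})

test_that("normalised pAUC of a perfect ranker is 1", {
  y <- rep(c(1, 0), each = 50)
  s <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(pauc01(y, s), 1)
  expect_equal(pauc01(y, s, normalised = FALSE), 0.1)
})

test_that("paired bootstrap comparison behaves at the extremes", {
  set.seed(83)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  s_perfect <- y + rnorm(n, sd = 0.01)
  s_anti <- -s_perfect
  # identical scores: no strict win is possible
  bc <- bootstrap_compare(y, s_perfect, s_perfect, n_rounds = 500, seed = 1)
  expect_equal(bc$wins, 0L)
  expect_equal(bc$p_value, 1)
  # perfect vs anti-perfect
  bc2 <- bootstrap_compare(y, s_perfect, s_anti, n_rounds = 1000, seed = 2)
  expect_lt(bc2$p_value, 0.01)
  # swap consistency and p1 + p2 >= 1
  s1 <- rnorm(n); s2 <- s1 + rnorm(n, sd = 0.5)
  b12 <- bootstrap_compare(y, s1, s2, n_rounds = 400, seed = 3)
  b21 <- bootstrap_compare(y, s2, s1, n_rounds = 400, seed = 3)
  expect_gte(b12$p_value + b21$p_value, 1)
  # same paired resampling: per-round AUCs swap exactly
  expect_equal(b12$auc_c1, b21$auc_c2, tolerance = 1e-12)
  expect_equal(b12$auc_c2, b21$auc_c1, tolerance = 1e-12)
})

test_that("the pooled proportions z-test reproduces the reference analyses", {
  # mutation-outside-ICORE depletion: 11/116 immunogenic vs 620/2917
  p <- proportions_ztest(11, 116, 620, 2917, alternative = "less")
  expect_equal(signif(p, 2), 0.0011) # two significant figures
  # equal proportions sit exactly at 0.5 either way
  expect_equal(proportions_ztest(30, 100, 60, 200, "less"), 0.5)
  expect_equal(proportions_ztest(30, 100, 60, 200, "greater"), 0.5)
  expect_error(proportions_ztest(1, 0, 2, 10), "n1 > 0")
})

test_that("the z-test agrees with the uncorrected prop.test route", {
  set.seed(84)
  for (i in 1:100) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
    x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    want <- suppressWarnings(stats::prop.test(
      c(x1, x2), c(n1, n2), alternative = "less", correct = FALSE))$p.value
    expect_equal(proportions_ztest(x1, n1, x2, n2, "less"), want,
                 tolerance = 1e-6)
  }
})

test_that("z-test p moves monotonically with the group-1 successes", {
  ps <- vapply(5:50, function(x) proportions_ztest(x, 116, 620, 2917, "less"),
               numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("one-sided Welch test handles shifts and degenerate input", {
  expect_equal(welch_ttest_onesided(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(welch_ttest_onesided(c(2, 2), c(2, 2)), 0.5)
  expect_equal(welch_ttest_onesided(c(3, 3), c(1, 1)), 0)
  set.seed(85)
  a <- rnorm(1000, 1); b <- rnorm(1000, 0)
  expect_lt(welch_ttest_onesided(a, b), 1e-10)
  # agrees with the direct Welch/Satterthwaite formula
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    t_stat <- (mean(x) - mean(y)) /
      sqrt(var(x) / length(x) + var(y) / length(y))
    df <- (var(x) / length(x) + var(y) / length(y))^2 /
      ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
    expect_equal(welch_ttest_onesided(x, y),
                 pt(t_stat, df, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("consensus selection ranks by harmonic mean, stably", {
  cand <- data.frame(model = c("a", "b", "c", "d"),
                     auc_primary = c(0.8, 1.0, 0.7, 0.9),
                     auc_external = c(0.8, 0.5, 0.7, 0.6))
  out <- select_consensus(cand)
  expect_equal(out$harmonic_mean[out$model == "a"], 0.8)
  expect_equal(out$harmonic_mean[out$model == "b"], 2 / 3, tolerance = 1e-12)
  expect_equal(out$model[1], "a")
  # ties keep input order
  tie <- data.frame(model = c("x", "y"), auc_primary = c(0.8, 0.8),
                    auc_external = c(0.6, 0.6))
  expect_equal(select_consensus(tie)$model, c("x", "y"))
  # harmonic never exceeds arithmetic mean
  set.seed(86)
  a <- runif(50, 0.4, 1); b <- runif(50, 0.4, 1)
  hm <- select_consensus(data.frame(auc_primary = a,
                                    auc_external = b))$harmonic_mean
  expect_true(all(hm <= sort((a + b) / 2, decreasing = TRUE)[1] + 1e-12))
  expect_true(all(2 * a * b / (a + b) <= (a + b) / 2 + 1e-12))
  expect_error(select_consensus(data.frame(auc_primary = 0,
                                           auc_external = 0.5)), "positive")
})
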