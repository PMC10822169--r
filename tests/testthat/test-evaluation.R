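pair_of <- function(ref, test) tibble::tibble(reference = ref, test = test)

test_that("agreement metrics: perfect, biased, and hand-computed cases", {
  p <- pair_of(c(0, 10, 20, 30), c(0, 10, 20, 30))
  m <- agreement_metrics(p)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$spearman, 1)

  b <- agreement_metrics(pair_of(c(0, 10, 20, 30), c(5, 15, 25, 35)))
  expect_equal(b$mae, 5)
  expect_equal(b$rmse, 5)
  expect_equal(b$r2, 1) # correlation variant ignores pure bias
  expect_equal(b$mean_diff, 5)
  expect_equal(b$sd_diff, 0)

  # worked example computed by hand: diffs 1, 2, -2, 3
  h <- agreement_metrics(pair_of(c(0, 10, 20, 30), c(1, 12, 18, 33)))
  expect_equal(h$mae, 2)
  expect_equal(h$rmse, sqrt(4.5))
  expect_equal(h$mean_diff, 1)
  expect_equal(h$sd_diff, sqrt(3.5))
})

test_that("identity-line R-squared penalizes bias while correlation variant does not", {
  p <- pair_of(c(0, 10, 20, 30), c(5, 15, 25, 35))
  expect_equal(agreement_metrics(p, r2 = "correlation")$r2, 1)
  expect_lt(agreement_metrics(p, r2 = "identity")$r2, 1)
})

test_that("constant series report NA correlations with a warning", {
  p <- pair_of(rep(10, 5), rep(12, 5))
  expect_warning(m <- agreement_metrics(p), "constant")
  expect_true(is.na(m$spearman))
  expect_true(is.na(m$r2))
  expect_equal(m$mae, 2)
})

test_that("RMSE is at least MAE on random pairs, equal iff |diff| constant", {
  withr::with_seed(4, {
    for (i in 1:50) {
      p <- pair_of(runif(40, 0, 90), runif(40, 0, 90))
      m <- agreement_metrics(p)
      expect_gte(m$rmse, m$mae - 1e-12)
    }
  })
  eqp <- agreement_metrics(pair_of(c(0, 10, 20), c(3, 7, 23))) # |diff| = 3
  expect_equal(eqp$rmse, eqp$mae)
})

test_that("difference-plot data uses the between-method mean and sd lines", {
  p <- pair_of(c(0, 10, 20, 30), c(0, 10, 20, 30))
  d <- difference_plot_data(p)
  expect_true(all(d$points$diff == 0))
  expect_equal(d$mean_line, 0)
  expect_equal(d$upper_line, 0)

  pc <- pair_of(c(0, 10, 20), c(4, 14, 24))
  dc <- difference_plot_data(pc)
  expect_equal(dc$mean_line, 4)
  expect_equal(dc$upper_line, 4) # constant offset: sd collapses
  expect_equal(dc$points$x, c(2, 12, 22))

  withr::with_seed(5, {
    pr <- pair_of(runif(200, 0, 90), runif(200, 0, 90))
    dr <- difference_plot_data(pr)
    expect_equal(dr$mean_line, mean(pr$test - pr$reference), tolerance = 1e-12)
    expect_equal(dr$upper_line - dr$mean_line, sd_pop(pr$test - pr$reference))
  })
})

test_that("friedman statistic matches the rank-formula oracle and its anchors", {
  # identical columns: no effect
  m0 <- matrix(rep(c(4, 5, 6, 7), 3), ncol = 3)
  r0 <- distance_effect_test(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # rank-sum formula oracle on a small fixed design
  m <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2), c(1, 2, 3), c(3, 1, 2),
             c(1, 2, 3), c(2, 1, 3), c(1, 2, 3))
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  R <- colSums(ranks)
  chi_oracle <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  rt <- distance_effect_test(m)
  expect_equal(rt$statistic, chi_oracle, tolerance = 1e-12)

  # constant added per distance, n = 20 matched units
  withr::with_seed(10, {
    base <- runif(20, 2, 10)
    shifted <- cbind(`2` = base + rnorm(20, 0, 0.5),
                     `2.5` = base + 1 + rnorm(20, 0, 0.5),
                     `3.5` = base + 2 + rnorm(20, 0, 0.5))
    expect_lt(distance_effect_test(shifted)$p_value, 0.05)
  })
  expect_error(distance_effect_test(list(a = 1:5, b = 1:4, c = 1:5)), "matched")
  expect_error(distance_effect_test(matrix(1:6, nrow = 2)), ">= 3")
})

test_that("post-hoc pairwise tests are Bonferroni-corrected over the pairs", {
  withr::with_seed(11, {
    base <- runif(15, 2, 10)
    m <- cbind(a = base, b = base + 2, c = base + 4)
    r <- distance_effect_test(m)
    expect_equal(nrow(r$posthoc), 3)
    expect_equal(r$posthoc$p_adj, pmin(1, r$posthoc$p_raw * 3))
  })
})

test_that("wilcoxon signed-rank matches an exact enumeration oracle", {
  # brute-force null enumeration of the signed-rank statistic for n = 8
  # (tie-free absolute differences so the exact distribution applies)
  x <- c(4.2, 5.1, 6.3, 4.8, 5.9, 6.8, 5.2, 4.1)
  d <- c(0.3, -0.4, 0.7, 0.8, 0.55, 0.9, 0.62, -0.25)
  y <- x - d
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  null_V <- as.matrix(signs) %*% r
  p_oracle <- mean(null_V >= V) + mean(null_V <= sum(r) - V)
  wt <- arm_difference_test(x, y)
  expect_equal(wt$statistic, V)
  expect_equal(wt$p_value, p_oracle, tolerance = 1e-12)
})

test_that("arm difference test: degenerate, powered, and null behavior", {
  expect_equal(arm_difference_test(1:10, 1:10)$p_value, 1)
  withr::with_seed(12, {
    a <- runif(50, 0, 90)
    b <- a + 3 + rnorm(50, 0, 1)
    expect_lt(arm_difference_test(a, b)$p_value, 0.01)
  })
})

test_that("normality battery flags violations and survives degenerate input", {
  withr::with_seed(13, {
    g <- rnorm(500)
    r <- normality_tests(g)
    expect_gt(r$shapiro_wilk$p_value, 0.05)
    expect_gt(r$kolmogorov_smirnov$p_value, 0.05)
    bimodal <- c(rnorm(250, -4), rnorm(250, 4))
    rb <- normality_tests(bimodal)
    expect_lt(rb$shapiro_wilk$p_value, 0.05)
    expect_lt(rb$kolmogorov_smirnov$p_value, 0.05)
  })
  expect_warning(rc <- normality_tests(rep(1, 10)), "constant")
  expect_true(is.na(rc$shapiro_wilk$p_value))
})

test_that("histogram counts conserve the sample and respect bin width", {
  h <- histogram_data(rep(45, 17), bin_width = 10)
  expect_equal(sum(h$count), 17)
  expect_equal(h$count[h$bin_left == 40], 17)
  expect_equal(sum(h$count > 0), 1)
  withr::with_seed(14, {
    x <- runif(5000, 0, 180)
    h2 <- histogram_data(x, bin_width = 5)
    expect_equal(sum(h2$count), 5000)
    # approximately flat: chi-square against uniform expectation
    expected <- 5000 / nrow(h2)
    chi <- sum((h2$count - expected)^2 / expected)
    expect_lt(chi, qchisq(0.999, df = nrow(h2) - 1))
  })
  expect_error(histogram_data(1:10, bin_width = 0), "positive")
  # boundary value 180 is counted
  expect_equal(sum(histogram_data(c(0, 90, 180), bin_width = 5)$count), 3)
})

test_that("aggregate report computes grouped mean and population sd", {
  reports <- tibble::tibble(
    angle = "alpha", arm = "L", distance = 2,
    subject = c("S1", "S2"), mae = c(4, 6), rmse = c(5, 7),
    r2 = c(0.99, 0.97), spearman = c(0.95, 0.96)
  )
  a <- aggregate_report(reports)
  expect_equal(a$mae_mean, 5)
  expect_equal(a$mae_sd, 1) # population sd of {4, 6}
  single <- aggregate_report(reports[1, ])
  expect_equal(single$mae_sd, 0)
})
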