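test_that("run_study returns the documented scenario summaries", {
  s <- run_study(
    gamma1 = c(0, 1), estimator = "binary", n_reps = 3,
    n_clusters = 30, B_ci = 1000, seed = 31
  )
  expect_s3_class(s, "mtram_study")
  expect_equal(nrow(s), 6L) # 2 scenarios x 3 effects
  expect_equal(
    names(s),
    c(
      "estimator", "gamma1", "effect", "true_mu", "mse", "mse_se",
      "ci_width", "ci_width_se", "coverage", "coverage_se", "n_reps",
      "n_failed"
    )
  )
  expect_equal(unique(s$effect), c("mu1", "mu2", "mu3"))
  expect_equal(s$true_mu[s$gamma1 == 1], c(0, 1, 2) / sqrt(2))
  expect_true(all(s$n_failed == 0))
  expect_true(all(s$coverage >= 0 & s$coverage <= 1))
  expect_true(all(s$mse > 0 & s$ci_width > 0))
})

test_that("run_study is reproducible from its base seed", {
  s1 <- run_study(
    gamma1 = 1, estimator = "continuous", n_reps = 2,
    n_clusters = 25, B_ci = 1000, seed = 77
  )
  s2 <- run_study(
    gamma1 = 1, estimator = "continuous", n_reps = 2,
    n_clusters = 25, B_ci = 1000, seed = 77
  )
  expect_equal(s1, s2)
})

test_that("study and fit plots build without error", {
  s <- run_study(
    gamma1 = c(0.5, 1), estimator = "binary", n_reps = 2,
    n_clusters = 25, B_ci = 1000, seed = 13
  )
  p <- plot_study(s)
  expect_s3_class(p, "ggplot")
  d <- simulate_clustered(n_clusters = 25, seed = 2)
  fit <- fit_mtram(d,
    response = "y", cluster = "cluster",
    covariates = c("x1", "x2", "x3"), order = 4,
    control = mtram_control(hessian = FALSE)
  )
  pa <- autoplot(fit, newdata = data.frame(x1 = c(0, 1), x2 = 0.5, x3 = 0.5))
  expect_s3_class(pa, "ggplot")
  expect_no_error(ggplot2::ggplot_build(pa))
})
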