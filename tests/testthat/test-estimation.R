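fit_small <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      d <- simulate_clustered(n_clusters = 40, gamma1 = 1, seed = 5)
      fit <<- fit_mtram(d,
        response = "y", cluster = "cluster",
        covariates = c("x1", "x2", "x3"), link = "logit",
        basis = "bernstein", order = 6
      )
    }
    fit
  }
})

test_that("fit_mtram converges with a small projected gradient", {
  fit <- fit_small()
  expect_equal(fit$convergence$code, 0L)
  expect_true(is.finite(fit$loglik))
  expect_lt(fit$convergence$projected_gradient_norm, 1e-1)
  # interior score is numerically zero at the optimum for free coordinates
  expect_true(all(diff(fit$theta) >= 0))
})

test_that("refitting from the solution is idempotent", {
  fit <- fit_small()
  d <- simulate_clustered(n_clusters = 40, gamma1 = 1, seed = 5)
  refit <- fit_mtram(d,
    response = "y", cluster = "cluster",
    covariates = c("x1", "x2", "x3"), link = "logit",
    basis = "bernstein", order = 6,
    control = mtram_control(init = fit$par, hessian = FALSE)
  )
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-7)
  expect_equal(refit$par, fit$par, tolerance = 1e-3)
})

test_that("independent data drive the copula parameter to zero", {
  d <- simulate_clustered(n_clusters = 60, gamma1 = 0, seed = 9)
  fit <- fit_mtram(d,
    response = "y", cluster = "cluster",
    covariates = c("x1", "x2", "x3"), link = "logit",
    basis = "bernstein", order = 6,
    control = mtram_control(hessian = FALSE)
  )
  expect_lt(fit$gamma[1], 0.25)
})

test_that("binary single-intercept fit recovers DGP-scale parameters", {
  d <- dichotomize_median(
    simulate_clustered(n_clusters = 250, gamma1 = 1, seed = 21)
  )
  fit <- fit_mtram(d,
    response = "y_bin", cluster = "cluster",
    covariates = c("x1", "x2", "x3"), link = "logit", basis = "binary"
  )
  mu_hat <- fit$beta / sqrt(1 + fit$gamma[1]^2)
  se <- sqrt(diag(fit$vcov))[2:4] / sqrt(1 + fit$gamma[1]^2)
  mu_true <- c(0, 1, 2) / sqrt(2)
  expect_true(all(abs(mu_hat - mu_true) < 4 * se + 0.15))
})

test_that("accessors and tidiers expose the fit consistently", {
  fit <- fit_small()
  expect_named(coef(fit))
  expect_equal(unname(logLik(fit))[1], fit$loglik, ignore_attr = TRUE)
  expect_equal(dim(vcov(fit)), c(11L, 11L))
  td <- tidy(fit)
  expect_equal(
    names(td),
    c("term", "block", "estimate", "std.error", "marginal")
  )
  expect_equal(sum(td$block == "fixed"), 3L)
  expect_equal(
    td$marginal[td$block == "fixed"],
    fit$beta / sqrt(1 + fit$gamma[1]^2)
  )
  gl <- glance(fit)
  expect_equal(gl$nobs, 200L)
  expect_equal(gl$n_clusters, 40L)
  expect_output(print(fit), "Marginal transformation model")
})

test_that("parameter chart round-trips and maps gradients correctly", {
  ch <- martram:::chart_spec(
    basis_spec("bernstein", order = 5, support = c(0, 1)),
    S = 1, R = 1
  )
  theta <- cumsum(c(-2, rexp(5)))
  free <- martram:::theta_to_free(ch, theta)
  expect_equal(martram:::free_to_theta(ch, free), theta, tolerance = 1e-12)
  g <- rnorm(6)
  expect_equal(
    martram:::grad_theta_to_free(ch, g),
    rev(cumsum(rev(g))),
    tolerance = 1e-12
  )
})
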