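fit_marg <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      d <- simulate_clustered(n_clusters = 50, gamma1 = 1, seed = 17)
      fit <<- fit_mtram(d,
        response = "y", cluster = "cluster",
        covariates = c("x1", "x2", "x3"), link = "logit",
        basis = "bernstein", order = 6
      )
    }
    fit
  }
})

test_that("marginal_cdf is a proper distribution function", {
  fit <- fit_marg()
  sup <- fit$spec$basis$support
  y <- c(-Inf, seq(sup[1], sup[2], length.out = 50), Inf)
  out <- marginal_cdf(fit, y, x = c(0.5, 0.5, 0.5))
  expect_equal(names(out), c("y", "cdf"))
  expect_equal(out$cdf[1], 0)
  expect_equal(out$cdf[nrow(out)], 1)
  expect_true(all(diff(out$cdf[is.finite(out$y)]) >= 0))
  expect_true(all(out$cdf >= 0 & out$cdf <= 1))
})

test_that("marginal effects shrink the latent coefficients", {
  fit <- fit_marg()
  me <- marginal_effects(fit)
  s <- sqrt(1 + fit$gamma[1]^2)
  expect_equal(me$marginal, fit$beta / s)
  expect_true(all(abs(me$marginal) <= abs(me$estimate) + 1e-12))
  expect_equal(me$scale, rep("log-odds ratio", 3))
  # with u = 0 rows the scale is 1 and nothing shrinks
  me0 <- marginal_effects(fit, u = 0)
  expect_equal(me0$marginal, me0$estimate)
})

test_that("simulation-based confidence intervals are reproducible and ordered", {
  fit <- fit_marg()
  me1 <- marginal_effects(fit, conf.int = TRUE, B = 2000, seed = 1)
  me2 <- marginal_effects(fit, conf.int = TRUE, B = 2000, seed = 1)
  expect_equal(me1, me2)
  expect_true(all(me1$conf.low < me1$conf.high))
  expect_true(all(me1$conf.low < me1$marginal & me1$marginal < me1$conf.high))
  expect_error(simulate_ci(fit, function(p) p[1], B = 10))
})

test_that("probabilistic index has its closed-form and symmetry properties", {
  fit <- fit_marg()
  x <- c(0.5, 0.5, 0.5)
  expect_equal(probabilistic_index(fit, x, x)$estimate, 0.5,
    tolerance = 1e-8
  )
  p12 <- probabilistic_index(fit, x + c(0, 0.3, 0), x)$estimate
  p21 <- probabilistic_index(fit, x, x + c(0, 0.3, 0))$estimate
  expect_equal(p12 + p21, 1, tolerance = 1e-7)
  expect_gt(p12, 0.5) # positive effect raises the index
})

test_that("probit probabilistic index matches the closed form", {
  d <- simulate_clustered(n_clusters = 30, gamma1 = 0.5, seed = 23)
  fit <- fit_mtram(d,
    response = "y", cluster = "cluster",
    covariates = c("x1", "x2", "x3"), link = "probit",
    basis = "bernstein", order = 5,
    control = mtram_control(hessian = FALSE)
  )
  x1 <- c(1, 0.6, 0)
  x2 <- c(0, 0.1, 0.4)
  s <- sqrt(1 + fit$gamma[1]^2)
  delta <- sum((x1 - x2) * fit$beta) / s
  expect_equal(
    probabilistic_index(fit, x1, x2)$estimate,
    pnorm(delta / sqrt(2)),
    tolerance = 1e-7
  )
})

test_that("marginal CDF matches forward simulation from the fitted model", {
  fit <- fit_marg()
  sp <- fit$spec
  sup <- sp$basis$support
  x <- c(0.5, 0.5, 0.5)
  set.seed(99)
  n <- 2e5
  # simulate from the latent mechanism: z ~ N(0, s^2) on the probit scale,
  # map through the copula margin and invert h on a fine grid
  s <- marginal_scale(1, fit$gamma)
  z <- rnorm(n, sd = s) # marginal latent score, variance u'LL'u + 1
  grid <- seq(sup[1], sup[2], length.out = 2^13)
  hg <- drop(basis_row(sp$basis, grid) %*% fit$theta) - sum(x * fit$beta)
  target <- s * qlogis(pnorm(z / s))
  ys <- approx(hg, grid, xout = pmin(pmax(target, hg[1]), hg[length(hg)]),
    ties = "ordered"
  )$y
  at <- seq(sup[1], sup[2], length.out = 101)
  emp <- ecdf(ys)(at)
  thr <- marginal_cdf(fit, at, x = x)$cdf
  expect_lt(max(abs(emp - thr)), 0.01)
})
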