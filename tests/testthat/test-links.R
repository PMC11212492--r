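test_that("link CDFs and quantiles are mutual inverses", {
  for (nm in c("probit", "logit", "cloglog", "loglog")) {
    # the cloglog CDF saturates to exactly 1 in double precision beyond
    # z ~ 3.6, where the probability-scale inverse is undefined
    z <- if (nm == "cloglog") seq(-5, 3, by = 0.25) else seq(-5, 5, by = 0.25)
    p <- inverse_link(nm, z)
    expect_true(all(diff(p) > 0), info = nm)
    expect_equal(link_quantile(nm, p), z, tolerance = 1e-8)
  }
})

test_that("link densities are derivatives of the CDFs", {
  z <- seq(-4, 4, by = 0.5)
  h <- 1e-5
  for (nm in c("probit", "logit", "cloglog", "loglog")) {
    num <- (inverse_link(nm, z + h) - inverse_link(nm, z - h)) / (2 * h)
    expect_equal(link_density(nm, z), num, tolerance = 1e-6)
  }
})

test_that("log CDF and log survivor branches are consistent", {
  z <- seq(-4, 4, by = 0.5)
  for (nm in c("probit", "logit", "cloglog", "loglog")) {
    lk <- link_family(nm)
    expect_equal(exp(lk$log_cdf(z)), lk$cdf(z), tolerance = 1e-12)
    expect_equal(exp(lk$log_cdf(z)) + exp(lk$log_sf(z)),
      rep(1, length(z)),
      tolerance = 1e-12
    )
    expect_equal(exp(lk$log_pdf(z)), lk$pdf(z), tolerance = 1e-12)
  }
})

test_that("dlog_pdf matches the numeric derivative of log_pdf", {
  z <- seq(-3, 3, by = 0.5)
  h <- 1e-6
  for (nm in c("probit", "logit", "cloglog", "loglog")) {
    lk <- link_family(nm)
    num <- (lk$log_pdf(z + h) - lk$log_pdf(z - h)) / (2 * h)
    expect_equal(lk$dlog_pdf(z), num, tolerance = 1e-5)
  }
})

test_that("cloglog and loglog are reflections of each other", {
  z <- seq(-3, 3, by = 0.25)
  expect_equal(inverse_link("cloglog", z),
    1 - inverse_link("loglog", -z),
    tolerance = 1e-12
  )
})

test_that("tail-safe normal quantile matches qnorm in both branches", {
  lk <- link_family("logit")
  m <- c(-30, -5, 0, 5, 30)
  q <- martram:::std_normal_quantile_of(lk, m)
  expect_equal(q[3], 0, tolerance = 1e-12)
  expect_true(all(is.finite(q)))
  expect_equal(pnorm(q[2]), plogis(m[2]), tolerance = 1e-10)
  # deep tails: compare on the log scale
  expect_equal(pnorm(q[1], log.p = TRUE), plogis(m[1], log.p = TRUE),
    tolerance = 1e-8
  )
})

test_that("invalid link names and boundary probabilities error", {
  expect_error(link_family("cauchit"))
  expect_error(link_quantile("logit", 0))
  expect_error(link_quantile("probit", 1))
})
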