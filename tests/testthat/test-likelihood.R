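# shared small instances --------------------------------------------------
make_cont <- function(n_clusters = 12, gamma1 = 1, seed = 3) {
  d <- simulate_clustered(
    n_clusters = n_clusters, cluster_size = 4,
    gamma1 = gamma1, seed = seed
  )
  list(
    y = d$y,
    X = as.matrix(d[c("x1", "x2", "x3")]),
    U = matrix(1, nrow(d), 1),
    cl = d$cluster,
    basis = basis_spec("bernstein", order = 4, support = range(d$y)),
    theta = cumsum(c(-3, rep(1.2, 4))),
    beta = c(0.1, 0.9, 1.8)
  )
}

test_that("analytic continuous score matches finite differences (R = 1)", {
  m <- make_cont()
  par <- c(m$theta, m$beta, 0.8)
  fn <- function(p) {
    loglik_continuous(
      m$y, m$X, m$U, m$cl, p[1:5], p[6:8], p[9],
      m$basis, "logit"
    )
  }
  num <- numDeriv::grad(fn, par)
  ana <- score_continuous(
    m$y, m$X, m$U, m$cl, par[1:5], par[6:8], par[9],
    m$basis, "logit"
  )
  expect_equal(unname(ana), num, tolerance = 1e-6)
})

test_that("analytic continuous score matches finite differences (R = 2)", {
  m <- make_cont()
  U <- cbind(1, rep(seq(0, 0.75, by = 0.25), 12))
  par <- c(m$theta, m$beta, c(0.7, 0.2, 0.4))
  fn <- function(p) {
    loglik_continuous(
      m$y, m$X, U, m$cl, p[1:5], p[6:8], p[9:11],
      m$basis, "probit"
    )
  }
  num <- numDeriv::grad(fn, par)
  ana <- score_continuous(
    m$y, m$X, U, m$cl, par[1:5], par[6:8], par[9:11],
    m$basis, "probit"
  )
  expect_equal(unname(ana), num, tolerance = 1e-6)
})

test_that("censored quadrature score matches finite differences", {
  m <- make_cont()
  med <- median(m$y)
  lo <- ifelse(m$y > med, med, -Inf)
  up <- ifelse(m$y > med, Inf, med)
  b <- basis_spec("binary_intercept")
  par <- c(2.1, 0.4, 1.1, 2.2, 1.3)
  fn <- function(p) {
    loglik_censored(lo, up, m$X, m$U, m$cl, p[1], p[2:4], p[5], b, "logit")
  }
  num <- numDeriv::grad(fn, par)
  ana <- score_censored(
    lo, up, m$X, m$U, m$cl, par[1], par[2:4], par[5], b,
    "logit"
  )
  expect_equal(unname(ana), num, tolerance = 1e-6)
})

test_that("mvn_rectangle agrees with mvtnorm on structured covariances", {
  set.seed(11)
  # random intercept, Ni = 5
  U <- matrix(1, 5, 1)
  lo <- rnorm(5, -1)
  up <- lo + rexp(5, 1 / 2)
  for (g in c(0.5, 1, 3)) {
    p_ref <- mvtnorm::pmvnorm(lo, up,
      sigma = sigma_build(U, g),
      algorithm = mvtnorm::GenzBretz(abseps = 1e-9, maxpts = 1e6)
    )
    expect_equal(mvn_rectangle(lo, up, U, g), as.numeric(p_ref),
      tolerance = 1e-5
    )
  }
  # random intercept + slope
  U2 <- cbind(1, 0:4)
  g2 <- c(0.6, 0.2, 0.5)
  p_ref <- mvtnorm::pmvnorm(lo, up,
    sigma = sigma_build(U2, g2),
    algorithm = mvtnorm::GenzBretz(abseps = 1e-9, maxpts = 1e6)
  )
  expect_equal(mvn_rectangle(lo, up, U2, g2), as.numeric(p_ref),
    tolerance = 1e-5
  )
})

test_that("mvn_rectangle is exact under independence", {
  lo <- c(-2, -1, 0)
  up <- c(1, 0.5, 2)
  expect_equal(
    mvn_rectangle(lo, up, matrix(1, 3, 1), gamma = 0),
    prod(pnorm(up) - pnorm(lo)),
    tolerance = 1e-14
  )
})

test_that("rule-doubling check reports non-convergence for coarse rules", {
  U2 <- cbind(1, seq(0, 3, length.out = 6))
  g2 <- c(1.5, 0.8, 1.2)
  lo <- rep(-0.2, 6)
  up <- rep(0.2, 6)
  expect_error(
    mvn_rectangle(lo, up, U2, g2, gh_nodes = 1L, tol = 1e-12),
    "rule-doubling"
  )
})

test_that("narrow-interval censored likelihood approaches the log-density", {
  m <- make_cont(n_clusters = 6)
  eps <- 1e-4
  # pad the support so no shrunken interval is clamped at the boundary
  basis <- basis_spec("bernstein", order = 4, support = range(m$y) + c(-1, 1))
  ll_c <- loglik_continuous(
    m$y, m$X, m$U, m$cl, m$theta, m$beta, 0.9,
    basis, "logit"
  )
  ll_i <- loglik_censored(
    m$y - eps / 2, m$y + eps / 2, m$X, m$U, m$cl,
    m$theta, m$beta, 0.9, basis, "logit",
    gh_nodes = 80L
  )
  n <- length(m$y)
  expect_equal(ll_i - n * log(eps), ll_c, tolerance = 1e-4)
})

test_that("latent_transform reproduces the marginal probit scores", {
  m <- make_cont(n_clusters = 4)
  z <- latent_transform(
    m$y, m$X, m$U, m$theta, m$beta, 1.5, m$basis,
    "logit"
  )
  d <- sqrt(1 + 1.5^2)
  h <- drop(basis_row(m$basis, m$y) %*% m$theta) - drop(m$X %*% m$beta)
  expect_equal(z, d * qnorm(plogis(h / d)), tolerance = 1e-12)
})
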