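#' Marginal distribution function implied by a fitted model
#'
#' The Gaussian copula model implies the closed-form marginal
#' transformation model \deqn{P(Y \le y \mid x, u) = F\!\left(\frac{a(y)^\top
#' \vartheta - x^\top\beta}{\sqrt{u^\top\Lambda\Lambda^\top u + 1}}\right),}
#' a valid CDF in \eqn{y} on the same interpretation scale \eqn{F} as the
#' univariate model — no numerical integration over random effects is
#' needed.
#'
#' @param fit An `mtram_fit`.
#' @param y Numeric vector of response values (\eqn{\pm}`Inf` allowed).
#' @param x Fixed-effect covariate vector (default: all zero, the baseline
#'   configuration).
#' @param u Random-effect covariate vector (default `c(1, 0, ...)`, a
#'   cluster-intercept row).
#' @param stratum Stratum index whose transformation to use (default 1).
#' @return A tibble with columns `y` and `cdf`.
#' @export
marginal_cdf <- function(fit, y, x = NULL, u = NULL, stratum = 1L) {
  sp <- fit$spec
  x <- x %||% numeric(sp$Q)
  u <- u %||% c(1, numeric(sp$R - 1L))
  s <- marginal_scale(u, fit$gamma)
  eta <- if (sp$Q) sum(x * fit$beta) else 0
  th <- fit$theta[(stratum - 1L) * sp$P + seq_len(sp$P)]
  p <- numeric(length(y))
  fin <- is.finite(y)
  p[!fin] <- as.numeric(y[!fin] > 0) # -Inf -> 0, Inf -> 1
  if (any(fin)) {
    h <- drop(basis_row(sp$basis, y[fin]) %*% th)
    p[fin] <- sp$link$cdf((h - eta) / s)
  }
  tibble::tibble(y = y, cdf = p)
}

#' Shrunken marginal effects
#'
#' Fixed effects divided by the latent marginal scale
#' \eqn{\sqrt{u^\top\Lambda\Lambda^\top u + 1}}: directly interpretable on
#' the scale fixed by the inverse link (log-odds ratios for logit,
#' log-hazard ratios for cloglog, ...). Since the scale is \eqn{\ge 1},
#' marginal effects are never larger in magnitude than the latent fixed
#' effects, with equality exactly when the random-effect variance
#' vanishes. Confidence intervals are obtained by simulating from the
#' asymptotic joint normal distribution of the estimates
#' (see [simulate_ci()]).
#'
#' @param fit An `mtram_fit`.
#' @param u Random-effect covariate vector (default cluster intercept).
#' @param conf.int Add simulation-based confidence intervals?
#' @param conf.level Confidence level.
#' @param B Number of draws for the intervals.
#' @param seed Optional seed for the draws.
#' @return A tibble with columns `term`, `estimate` (latent \eqn{\beta}),
#'   `marginal` (\eqn{\mu}), `scale` (the interpretation scale name) and,
#'   if requested, `conf.low` / `conf.high` for the marginal effect.
#' @export
marginal_effects <- function(fit, u = NULL, conf.int = FALSE,
                             conf.level = 0.95, B = 10000L, seed = NULL) {
  sp <- fit$spec
  u <- u %||% c(1, numeric(sp$R - 1L))
  s <- marginal_scale(u, fit$gamma)
  out <- tibble::tibble(
    term = sp$covariates,
    estimate = fit$beta,
    marginal = fit$beta / s,
    scale = sp$link$scale_name
  )
  if (conf.int) {
    Ptot <- sp$P * sp$S
    ci <- purrr::map(seq_len(sp$Q), function(q) {
      f <- function(draws) {
        gam <- draws[, Ptot + sp$Q + seq_len(sp$M), drop = FALSE]
        sc <- apply(gam, 1L, function(g) marginal_scale(u, g))
        draws[, Ptot + q] / sc
      }
      simulate_ci(fit, f, B = B, level = conf.level, seed = seed)
    })
    out$conf.low <- purrr::map_dbl(ci, "conf.low")
    out$conf.high <- purrr::map_dbl(ci, "conf.high")
  }
  out
}

#' Simulation-based confidence interval for a parameter functional
#'
#' Draws `B` samples from the asymptotic joint normal distribution
#' \eqn{N(\hat\eta, \widehat{\mathrm{cov}})} of all model parameters,
#' applies the functional to each draw, and returns empirical quantiles.
#' Draws of diagonal Cholesky entries of \eqn{\Lambda} are truncated at
#' the boundary 0. This is the interval construction used for marginal
#' effects, marginal hazard ratios and probabilistic indices, where the
#' delta method would require derivatives of nonlinear functionals.
#'
#' @param fit An `mtram_fit` with an available covariance.
#' @param functional A function. It is first offered the whole `B x npar`
#'   draw matrix (columns named as `fit$par`) and must then return a
#'   length-`B` vector; if it errors or returns a scalar it is applied
#'   row-wise to named parameter vectors instead.
#' @param B Number of draws (>= 1000).
#' @param level Confidence level.
#' @param seed Optional seed.
#' @return A tibble with `estimate` (functional at the point estimates),
#'   `conf.low`, `conf.high`, `level`, `B`.
#' @export
simulate_ci <- function(fit, functional, B = 10000L, level = 0.95,
                        seed = NULL) {
  stopifnot(B >= 1000L)
  V <- fit$vcov %||% vcov_observed(fit)
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_mvn(B, unname(fit$par), V)
  colnames(draws) <- names(fit$par)
  # truncate covariance diagonals at their boundary
  diag_idx <- fit$spec$P * fit$spec$S + fit$spec$Q +
    cumsum(seq_len(fit$spec$R))
  draws[, diag_idx] <- pmax(draws[, diag_idx, drop = FALSE], 0)
  vals <- tryCatch(
    {
      v <- functional(draws)
      if (length(v) != B) stop("not vectorised")
      v
    },
    error = function(e) {
      apply(draws, 1L, function(r) {
        tryCatch(functional(r), error = function(e2) NA_real_)
      })
    }
  )
  n_fail <- sum(!is.finite(vals))
  if (n_fail > 0.01 * B) {
    stop("functional failed on ", n_fail, " of ", B, " draws.",
      call. = FALSE
    )
  }
  a <- (1 - level) / 2
  qs <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  est <- tryCatch(
    {
      v <- functional(matrix(fit$par, 1L,
        dimnames = list(NULL, names(fit$par))
      ))
      if (length(v) != 1L) stop("x")
      v
    },
    error = function(e) functional(fit$par)
  )
  tibble::tibble(
    estimate = est, conf.low = qs[1L], conf.high = qs[2L],
    level = level, B = B
  )
}

# multivariate normal draws from a PSD covariance (eigen fallback when the
# Cholesky fails on a boundary-degenerate matrix)
draw_mvn <- function(B, mean, V) {
  n <- length(mean)
  Rt <- tryCatch(chol(V), error = function(e) {
    ei <- eigen(V, symmetric = TRUE)
    t(ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), n))
  })
  matrix(rnorm(B * n), B, n) %*% Rt +
    matrix(mean, B, n, byrow = TRUE)
}

#' Marginal probabilistic index
#'
#' \eqn{P(Y_1 > Y_2)} for independent draws from the marginal
#' distributions at covariate rows `x1` and `x2` (same random-effect row
#' `u`): the probability that a randomly chosen subject with covariates
#' `x1` has the larger response. Both margins share the baseline
#' transformation, so on the latent scale the index reduces to the
#' one-dimensional integral \eqn{\int f(t)\,F(t + \delta/s)\,dt} with
#' \eqn{\delta = (x_1 - x_2)^\top \beta} and \eqn{s} the marginal scale.
#'
#' @param fit An `mtram_fit` with a continuous basis.
#' @param x1,x2 Covariate vectors of the two groups.
#' @param u Random-effect covariate vector.
#' @param conf.int Add a simulation-based confidence interval?
#' @param conf.level,B,seed Passed to [simulate_ci()].
#' @return A tibble with `estimate` (and interval columns if requested).
#' @export
probabilistic_index <- function(fit, x1, x2, u = NULL, conf.int = FALSE,
                                conf.level = 0.95, B = 10000L,
                                seed = NULL) {
  sp <- fit$spec
  u <- u %||% c(1, numeric(sp$R - 1L))
  Ptot <- sp$P * sp$S
  pi_of <- function(beta, gamma) {
    s <- marginal_scale(u, gamma)
    delta <- sum((x1 - x2) * beta) / s
    ig <- stats::integrate(
      function(t) sp$link$pdf(t) * sp$link$cdf(t + delta),
      -Inf, Inf,
      rel.tol = 1e-9
    )
    if (ig$message != "OK") {
      stop("probabilistic-index quadrature failed: ", ig$message,
        call. = FALSE
      )
    }
    ig$value
  }
  est <- pi_of(fit$beta, fit$gamma)
  out <- tibble::tibble(estimate = est)
  if (conf.int) {
    f <- function(par) {
      pi_of(
        par[Ptot + seq_len(sp$Q)],
        par[Ptot + sp$Q + seq_len(sp$M)]
      )
    }
    ci <- simulate_ci(fit, f, B = B, level = conf.level, seed = seed)
    out$conf.low <- ci$conf.low
    out$conf.high <- ci$conf.high
    out$level <- conf.level
  }
  out
}
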