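# ---- free-parameter chart --------------------------------------------------
#
# All monotonicity / positivity constraints of the model are linear and can
# be made simple box constraints after a change of variables:
#   * bernstein / ordinal_steps: theta = cumsum(free), increments >= eps
#   * linear: slope coefficient >= eps; loglinear: log-slope >= eps
#   * gamma: diagonal Cholesky entries >= 0 (boundary gamma = 0 attainable)

chart_spec <- function(basis, S, R, eps = 1e-8) {
  P <- basis$n_param
  cummap <- basis$kind %in% c("bernstein", "ordinal_steps")
  lower_block <- switch(basis$kind,
    bernstein = ,
    ordinal_steps = c(-Inf, rep(eps, P - 1L)),
    linear = c(eps, -Inf),
    loglinear = c(-Inf, eps),
    binary_intercept = -Inf
  )
  diag_idx <- cumsum(seq_len(R))
  g_lower <- rep(-Inf, R * (R + 1L) / 2L)
  g_lower[diag_idx] <- 0
  list(
    P = P, S = S, cummap = cummap,
    lower = c(rep(lower_block, S), g_lower)
  )
}

theta_to_free <- function(ch, theta) {
  if (!ch$cummap) {
    return(theta)
  }
  unlist(lapply(split(theta, rep(seq_len(ch$S), each = ch$P)), function(t) {
    c(t[1L], diff(t))
  }), use.names = FALSE)
}

free_to_theta <- function(ch, free) {
  if (!ch$cummap) {
    return(free)
  }
  unlist(lapply(split(free, rep(seq_len(ch$S), each = ch$P)), cumsum),
    use.names = FALSE
  )
}

grad_theta_to_free <- function(ch, g) {
  if (!ch$cummap) {
    return(g)
  }
  unlist(lapply(split(g, rep(seq_len(ch$S), each = ch$P)), function(gg) {
    rev(cumsum(rev(gg)))
  }), use.names = FALSE)
}

split_par <- function(model, par) {
  Ptot <- model$Ptot
  Q <- ncol(model$X)
  list(
    theta = par[seq_len(Ptot)],
    beta = par[Ptot + seq_len(Q)],
    gamma = par[Ptot + Q + seq_len(model$M)]
  )
}

model_ll <- function(model, theta, beta, gamma, want_score = FALSE) {
  if (model$kind == "continuous") {
    ll_continuous_engine(model, theta, beta, gamma, want_score)
  } else {
    ll_censored_engine(model, theta, beta, gamma, want_score)
  }
}

# objective/gradient pair on the free chart; defined at top level (not as
# per-fit closures) and sharing one cached engine evaluation per iterate,
# since L-BFGS-B requests fn and gr at the same point
unpack_free <- function(fm, ctx) {
  ff <- ctx$free_full
  ff[ctx$mask] <- fm
  list(
    theta = free_to_theta(ctx$ch, ff[seq_len(ctx$model$Ptot)]),
    beta = ff[ctx$model$Ptot + seq_len(ctx$Q)],
    gamma = ff[ctx$model$Ptot + ctx$Q + seq_len(ctx$model$M)]
  )
}

obj_eval <- function(fm, ctx) {
  if (!is.null(ctx$last_fm) && identical(fm, ctx$last_fm)) {
    return(ctx$last_res)
  }
  p <- unpack_free(fm, ctx)
  res <- model_ll(ctx$model, p$theta, p$beta, p$gamma, want_score = TRUE)
  ctx$last_fm <- fm
  ctx$last_res <- res
  res
}

obj_fn <- function(fm, ctx) {
  ll <- obj_eval(fm, ctx)$ll
  if (!is.finite(ll)) 1e10 else -ll
}

obj_gr <- function(fm, ctx) {
  res <- obj_eval(fm, ctx)
  if (!is.finite(res$ll)) {
    return(numeric(sum(ctx$mask)))
  }
  g <- res$score
  gfree <- c(
    grad_theta_to_free(ctx$ch, g[seq_len(ctx$model$Ptot)]),
    g[ctx$model$Ptot + seq_len(ctx$Q)],
    g[ctx$model$Ptot + ctx$Q + seq_len(ctx$model$M)]
  )
  -gfree[ctx$mask]
}

# maximize the log-likelihood over the free chart; with `fix_gamma` the
# covariance parameters are held at their initial values (the independence
# start)
optimize_model <- function(model, init, control, fix_gamma = FALSE) {
  ch <- chart_spec(model$basis, model$S, model$R, control$eps)
  Q <- ncol(model$X)
  free0 <- c(theta_to_free(ch, init$theta), init$beta, init$gamma)
  lower <- c(ch$lower[seq_len(model$Ptot)], rep(-Inf, Q),
    utils::tail(ch$lower, model$M))
  mask <- rep(TRUE, length(free0))
  if (fix_gamma) mask[model$Ptot + Q + seq_len(model$M)] <- FALSE
  free_full <- pmax(free0, lower + 0) # project onto the box
  ctx <- new.env(parent = emptyenv())
  ctx$model <- model
  ctx$ch <- ch
  ctx$Q <- Q
  ctx$mask <- mask
  ctx$free_full <- free_full
  ctx$last_fm <- NULL
  opt <- stats::optim(
    par = free_full[mask], fn = obj_fn, gr = obj_gr, ctx = ctx,
    method = "L-BFGS-B", lower = lower[mask],
    control = list(maxit = control$maxit, factr = control$factr)
  )
  p <- unpack_free(opt$par, ctx)
  grad <- tryCatch(obj_gr(opt$par, ctx),
    error = function(e) rep(NA_real_, sum(mask))
  )
  # projected gradient: at an active lower bound a positive gradient of the
  # negative log-likelihood is admissible
  at_bound <- is.finite(lower[mask]) & (opt$par <= lower[mask] + 1e-12)
  pg <- grad
  pg[at_bound] <- pmin(pg[at_bound], 0)
  list(
    par = c(p$theta, p$beta, p$gamma),
    loglik = -opt$value,
    convergence = list(
      code = opt$convergence, message = opt$message,
      iterations = opt$counts[["function"]],
      projected_gradient_norm = max(abs(pg)),
      active_bounds = sum(at_bound)
    )
  )
}

# ---- initial values --------------------------------------------------------

#' Starting values for marginal transformation model fits
#'
#' Builds a feasible parameter vector: transformation coefficients from a
#' method-of-moments / empirical-quantile match under independence, zero
#' fixed effects refined by an independence fit (\eqn{\gamma = 0}, which
#' decouples clusters), and covariance parameters started at 0.1 on the
#' Cholesky diagonal.
#'
#' @param model Internal model object (as built by [fit_mtram()]); exposed
#'   for completeness, most users call [fit_mtram()] directly.
#' @param control A [mtram_control()] list.
#' @return List with elements `theta`, `beta`, `gamma`.
#' @keywords internal
#' @export
initial_values <- function(model, control = mtram_control()) {
  link <- model$link
  basis <- model$basis
  P <- model$P
  if (model$kind == "continuous") {
    yy <- model$y
  } else {
    mid <- ifelse(model$fin_lo & model$fin_up,
      (model$lo + model$up) / 2,
      ifelse(model$fin_lo, model$lo, model$up)
    )
    yy <- mid[is.finite(mid)]
  }
  ec <- function(y0) {
    n <- length(yy)
    pmin(pmax(mean(yy <= y0), 1 / (n + 1)), n / (n + 1))
  }
  theta0 <- switch(basis$kind,
    bernstein = {
      xi <- seq(basis$support[1L], basis$support[2L], length.out = P)
      t0 <- link$quantile(vapply(xi, ec, 0))
      t0 <- cummax(t0 + seq_len(P) * 1e-3) # strictly increasing
      t0
    },
    linear = c(1 / stats::sd(yy), mean(yy) / stats::sd(yy)),
    loglinear = {
      tgt <- link$quantile(vapply(yy, ec, 0))
      fit <- stats::lm.fit(cbind(1, log(yy)), tgt)
      cf <- fit$coefficients
      if (!is.finite(cf[2L]) || cf[2L] <= 0) cf <- c(0, 1)
      cf
    },
    binary_intercept = {
      p0 <- mean(!model$fin_lo) # share of (-Inf, cut] observations
      link$quantile(pmin(pmax(p0, 0.02), 0.98))
    },
    ordinal_steps = {
      cum <- cumsum(tabulate(match(yy, seq_len(P + 1L)), P + 1L))
      pr <- pmin(pmax(cum[seq_len(P)] / length(yy), 0.02), 0.98)
      cummax(link$quantile(pr) + seq_len(P) * 1e-3)
    }
  )
  theta0 <- rep(theta0, model$S)
  beta0 <- numeric(ncol(model$X))
  gamma0 <- numeric(model$M)
  # refine theta, beta under independence
  ind <- optimize_model(model,
    list(theta = theta0, beta = beta0, gamma = gamma0),
    control,
    fix_gamma = TRUE
  )
  p <- split_par(model, ind$par)
  if (!is.finite(ind$loglik)) {
    stop("independence starting fit failed to produce a finite ",
      "log-likelihood.",
      call. = FALSE
    )
  }
  diag_idx <- cumsum(seq_len(model$R))
  p$gamma[diag_idx] <- 0.1
  p
}

# ---- control + main fitting function ---------------------------------------

#' Control parameters for [fit_mtram()]
#'
#' @param maxit Maximum optimizer iterations.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @param eps Lower bound used for positivity-constrained coefficients.
#' @param gh_nodes Gauss-Hermite nodes per latent dimension for censored
#'   likelihoods.
#' @param hessian Compute the observed-information covariance (`TRUE` by
#'   default; skipping it speeds up large simulation runs that only need
#'   point estimates).
#' @param init Optional full starting vector \eqn{(\vartheta, \beta,
#'   \gamma)}; by default starting values are constructed by
#'   [initial_values()].
#' @return A list of control settings.
#' @export
mtram_control <- function(maxit = 500L, factr = 1e7, eps = 1e-8,
                          gh_nodes = 40L, hessian = TRUE, init = NULL) {
  list(
    maxit = maxit, factr = factr, eps = eps, gh_nodes = gh_nodes,
    hessian = hessian, init = init
  )
}

#' Fit a marginally interpretable transformation model
#'
#' Maximum-likelihood estimation of the Gaussian-copula transformation
#' model for clustered data: marginal linear transformation models
#' \eqn{F(h(y) - x^\top\beta)} coupled through a latent multivariate
#' normal with covariance \eqn{U\Lambda\Lambda^\top U^\top + I}. Exactly
#' observed continuous responses use the log-density likelihood with
#' analytic scores; binary, ordinal and interval-censored responses use
#' the exact rectangle-probability likelihood.
#'
#' @param data A data frame or a [clustered_data()] tibble.
#' @param response,lower,upper,cluster,covariates,time,strata Column names
#'   passed to [clustered_data()] when `data` is a plain data frame.
#' @param link Inverse link family name or [link_family()].
#' @param basis Basis kind: `"bernstein"`, `"linear"`, `"loglinear"`,
#'   `"binary"` or `"ordinal"`.
#' @param order Bernstein degree (default 6).
#' @param support Response interval for the Bernstein basis; defaults to
#'   the range of the finite observed bounds.
#' @param control A [mtram_control()] list.
#' @return An object of class `mtram_fit` with components `par` (named
#'   estimates), `theta`, `beta`, `gamma`, `loglik`, `vcov`, `spec`,
#'   `convergence` and the standardised `data`. Methods: `print()`,
#'   `coef()`, `logLik()`, `vcov()`, [tidy()][generics::tidy],
#'   [glance()][generics::glance], [autoplot()][ggplot2::autoplot].
#' @examples
#' set.seed(1)
#' d <- simulate_clustered(n_clusters = 30, gamma1 = 1, seed = 1)
#' f <- fit_mtram(d,
#'   response = "y", cluster = "cluster",
#'   covariates = c("x1", "x2", "x3"), link = "logit", order = 4
#' )
#' glance(f)
#' @export
fit_mtram <- function(data, response = NULL, lower = NULL, upper = NULL,
                      cluster = NULL, covariates = NULL, time = NULL,
                      strata = NULL,
                      link = "logit",
                      basis = c(
                        "bernstein", "linear", "loglinear", "binary",
                        "ordinal"
                      ),
                      order = 6L, support = NULL,
                      control = mtram_control()) {
  basis_kind <- match.arg(basis)
  if (!inherits(data, "clustered_df")) {
    data <- clustered_data(data,
      cluster = cluster, response = response,
      lower = lower, upper = upper,
      covariates = covariates %||% character(),
      time = time, strata = strata
    )
  }
  sch <- attr(data, "schema")
  covs <- sch$covariates
  lo <- data$.lower
  up <- data$.upper
  exact <- data$.exact
  n <- nrow(data)

  if (basis_kind == "binary") {
    yv <- lo
    if (!all(exact) || !all(yv %in% c(0, 1))) {
      stop("binary basis expects an exactly observed 0/1 response.",
        call. = FALSE
      )
    }
    bs <- basis_spec("binary_intercept")
    lo <- ifelse(yv == 1, 0.5, -Inf) # finite value hits the single cut
    up <- ifelse(yv == 1, Inf, 0.5)
    exact <- rep(FALSE, n)
  } else if (basis_kind == "ordinal") {
    yv <- as.integer(lo)
    K <- max(yv)
    if (!all(exact) || !all(yv %in% seq_len(K))) {
      stop("ordinal basis expects integer-coded levels 1..K.", call. = FALSE)
    }
    bs <- basis_spec("ordinal_steps", n_levels = K)
    lo <- ifelse(yv == 1L, -Inf, yv - 1)
    up <- ifelse(yv == K, Inf, yv)
    exact <- rep(FALSE, n)
  } else if (basis_kind == "bernstein") {
    fin <- c(lo[is.finite(lo)], up[is.finite(up)])
    bs <- basis_spec("bernstein",
      order = order,
      support = support %||% range(fin)
    )
  } else {
    bs <- basis_spec(basis_kind,
      support = support
    )
  }

  U <- if (".time" %in% names(data)) cbind(1, data$.time) else matrix(1, n, 1L)
  X <- if (length(covs)) as.matrix(data[covs]) else NULL
  strata_id <- if (".stratum" %in% names(data)) {
    as.integer(data$.stratum)
  } else {
    NULL
  }
  model <- build_model(lo, up, exact, X, U,
    as.integer(data$.cluster),
    link, bs,
    strata = strata_id, gh_nodes = control$gh_nodes
  )
  init <- if (!is.null(control$init)) {
    split_par(model, as.numeric(control$init))
  } else {
    initial_values(model, control)
  }
  res <- optimize_model(model, init, control, fix_gamma = FALSE)
  p <- split_par(model, res$par)

  theta_names <- paste0("h", seq_len(model$P))
  if (model$S > 1L) {
    theta_names <- paste0(
      rep(levels(data$.stratum), each = model$P), ":",
      rep(theta_names, model$S)
    )
  }
  par_names <- c(theta_names, covs, paste0("gamma", seq_len(model$M)))
  names(res$par) <- par_names

  fit <- structure(
    list(
      par = res$par, theta = p$theta, beta = p$beta, gamma = p$gamma,
      loglik = res$loglik, vcov = NULL,
      spec = list(
        link = as_link(link), basis = bs, covariates = covs,
        longitudinal = ".time" %in% names(data),
        R = model$R, P = model$P, Q = ncol(model$X), M = model$M,
        S = model$S, basis_kind = basis_kind
      ),
      convergence = res$convergence,
      model = model, data = data
    ),
    class = "mtram_fit"
  )
  if (isTRUE(control$hessian)) {
    fit$vcov <- vcov_observed(fit)
  }
  fit
}

#' Observed-information covariance of a fitted model
#'
#' Inverse of the numerically differentiated negative Hessian of the total
#' log-likelihood at the maximum (the observed Fisher information). The
#' Hessian is obtained as the Jacobian of the analytic (continuous) or
#' quadrature (censored) score and symmetrised. When inversion fails, a
#' pseudo-inverse on the nondegenerate eigenspace is returned with a
#' warning carrying the eigenvalue diagnostics.
#'
#' @param fit An `mtram_fit`.
#' @return A symmetric covariance matrix over
#'   \eqn{(\vartheta, \beta, \gamma)}.
#' @export
vcov_observed <- function(fit) {
  model <- fit$model
  sc <- function(par) {
    p <- split_par(model, par)
    model_ll(model, p$theta, p$beta, p$gamma, want_score = TRUE)$score
  }
  par <- unname(fit$par)
  np <- length(par)
  # the gamma Cholesky diagonal is constrained to be nonnegative; at a
  # boundary optimum the backward step would leave the parameter space
  lo_par <- rep(-Inf, np)
  lo_par[model$Ptot + ncol(model$X) + cumsum(seq_len(model$R))] <- 0
  sc0 <- NULL
  J <- matrix(NA_real_, np, np)
  for (i in seq_len(np)) {
    h <- 1e-5 * max(1, abs(par[i]))
    e <- numeric(np)
    e[i] <- h
    if (par[i] - h < lo_par[i]) {
      if (is.null(sc0)) sc0 <- sc(par)
      J[, i] <- (sc(par + e) - sc0) / h
    } else {
      J[, i] <- (sc(par + e) - sc(par - e)) / (2 * h)
    }
  }
  H <- -(J + t(J)) / 2
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(diag(out) < 0)) {
    ei <- eigen(H, symmetric = TRUE)
    keep <- ei$values > max(ei$values) * 1e-10
    warning(
      "observed information is singular or indefinite (eigenvalues ",
      paste(signif(range(ei$values), 3), collapse = " .. "),
      "); returning a pseudo-inverse.",
      call. = FALSE
    )
    out <- ei$vectors[, keep, drop = FALSE] %*%
      (t(ei$vectors[, keep, drop = FALSE]) / ei$values[keep])
  }
  out <- (out + t(out)) / 2
  dimnames(out) <- list(names(fit$par), names(fit$par))
  out
}

# ---- standard S3 methods ---------------------------------------------------

#' @export
print.mtram_fit <- function(x, ...) {
  cat(
    "Marginal transformation model (", x$spec$link$name, " link, ",
    x$spec$basis$kind, " basis)\n",
    sep = ""
  )
  cat("log-likelihood:", format(x$loglik, digits = 8), "\n")
  if (length(x$beta)) {
    cat("fixed effects (latent scale):\n")
    print(stats::setNames(x$beta, x$spec$covariates))
  }
  cat("covariance parameters:", paste(signif(x$gamma, 4), collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' @export
coef.mtram_fit <- function(object, ...) object$par

#' @export
logLik.mtram_fit <- function(object, ...) {
  structure(object$loglik,
    df = length(object$par),
    nobs = object$model$n, class = "logLik"
  )
}

#' @export
vcov.mtram_fit <- function(object, ...) {
  object$vcov %||% vcov_observed(object)
}
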