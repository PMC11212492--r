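# ---- internal model container ----------------------------------------------
#
# A "model" is a plain list bundling the data in fitting shape:
#   kind      "continuous" or "censored"
#   link      link_family; basis  basis_spec
#   n, ncl, cluster (integer 1..ncl), X (n x Q), U (n x R), R, M
#   strata (integer 1..S), S, P (per stratum), Ptot = P * S
#   continuous: y, A, Ad           (n x Ptot, strata-expanded)
#   censored:   lo, up, A_lo, A_up, fin_lo, fin_up
#   gh: list(smat K x R, lw length K)   quadrature rule

expand_strata <- function(A0, strata, S) {
  if (S == 1L) {
    return(A0)
  }
  P <- ncol(A0)
  out <- matrix(0, nrow(A0), P * S)
  for (s in seq_len(S)) {
    rows <- which(strata == s)
    out[rows, (s - 1L) * P + seq_len(P)] <- A0[rows, , drop = FALSE]
  }
  out
}

build_model <- function(lower, upper, exact, X, U, cluster, link, basis,
                        strata = NULL, gh_nodes = 40L) {
  n <- length(lower)
  link <- as_link(link)
  cluster <- as.integer(factor(cluster, levels = unique(cluster)))
  X <- if (is.null(X)) matrix(0, n, 0L) else as.matrix(X)
  U <- as.matrix(U)
  R <- ncol(U)
  strata <- if (is.null(strata)) rep(1L, n) else as.integer(strata)
  S <- max(strata)
  kind <- if (all(exact)) "continuous" else "censored"
  if (!all(exact) && any(exact)) {
    stop("clusters mixing exact and censored observations are not ",
      "supported; the likelihood requires all-exact or all-bounded data.",
      call. = FALSE
    )
  }
  m <- list(
    kind = kind, link = link, basis = basis, n = n,
    cluster = cluster, ncl = max(cluster), X = X, U = U, R = R,
    M = R * (R + 1L) / 2L, strata = strata, S = S, P = basis$n_param,
    Ptot = basis$n_param * S
  )
  if (kind == "continuous") {
    m$y <- lower
    m$A <- expand_strata(basis_row(basis, lower), strata, S)
    m$Ad <- expand_strata(basis_deriv_row(basis, lower), strata, S)
  } else {
    stopifnot(all(lower <= upper))
    m$lo <- lower
    m$up <- upper
    m$fin_lo <- is.finite(lower)
    m$fin_up <- is.finite(upper)
    A_lo <- matrix(0, n, m$Ptot)
    A_up <- matrix(0, n, m$Ptot)
    if (any(m$fin_lo)) {
      A_lo[m$fin_lo, ] <- expand_strata(
        basis_row(basis, lower[m$fin_lo]),
        strata[m$fin_lo], S
      )[, , drop = FALSE]
    }
    if (any(m$fin_up)) {
      A_up[m$fin_up, ] <- expand_strata(
        basis_row(basis, upper[m$fin_up]),
        strata[m$fin_up], S
      )[, , drop = FALSE]
    }
    m$A_lo <- A_lo
    m$A_up <- A_up
    m$gh <- gh_rule(R, gh_nodes)
  }
  m
}

gh_rule <- function(R, n_nodes) {
  g1 <- gauss_hermite_normal(n_nodes)
  if (R == 1L) {
    list(smat = matrix(g1$nodes, ncol = 1L), lw = log(g1$weights))
  } else if (R == 2L) {
    grid <- expand.grid(a = seq_len(n_nodes), b = seq_len(n_nodes))
    list(
      smat = cbind(g1$nodes[grid$a], g1$nodes[grid$b]),
      lw = log(g1$weights[grid$a]) + log(g1$weights[grid$b])
    )
  } else {
    stop("random-effect dimensions beyond 2 are not supported.",
      call. = FALSE
    )
  }
}

# ---- latent transform ------------------------------------------------------

#' Latent Gaussian transform of responses
#'
#' Maps responses (or censoring bounds) to the latent multivariate-normal
#' scale: \deqn{z(y) = D\,\Phi^{-1}(F(D^{-1}[A(y)\vartheta - X\beta]))}
#' with \eqn{D} the diagonal latent scaling. Infinite bounds map to
#' \eqn{\pm\infty}. For the probit link the transform reduces exactly to
#' \eqn{A(y)\vartheta - X\beta}.
#'
#' @param y Numeric vector of responses or bounds (\eqn{\pm}`Inf` allowed).
#' @param X Fixed-effect design matrix (rows aligned with `y`), or `NULL`.
#' @param U Random-effect design matrix (rows aligned with `y`).
#' @param theta,beta,gamma Parameter blocks (transformation coefficients,
#'   fixed effects, covariance parameters).
#' @param basis A [basis_spec()].
#' @param link A [link_family()] or family name.
#' @return Numeric vector `z` of the same length as `y`.
#' @export
latent_transform <- function(y, X, U, theta, beta, gamma, basis, link) {
  link <- as_link(link)
  U <- as.matrix(U)
  L <- cholesky_factor(gamma, R = ncol(U))
  d <- obs_scales(U, L)
  z <- rep(NA_real_, length(y))
  inf <- !is.finite(y)
  z[inf] <- y[inf]
  if (any(!inf)) {
    h <- drop(basis_row(basis, y[!inf]) %*% theta)
    eta <- if (is.null(X) || length(beta) == 0L) {
      0
    } else {
      drop(as.matrix(X)[!inf, , drop = FALSE] %*% beta)
    }
    m <- (h - eta) / d[!inf]
    z[!inf] <- d[!inf] * std_normal_quantile_of(link, m)
  }
  if (any(is.na(z))) {
    stop("non-finite latent transform; check parameters and support.",
      call. = FALSE
    )
  }
  z
}

# transform of one bound vector inside the engine; returns list with
# m, q, z, w = f(m)/phi(q), dlf = (f'/f)(m), only at `fin` positions
transform_bound <- function(model, A, bound_vals, fin, h_eta_d) {
  n <- model$n
  out <- list(
    m = rep(NA_real_, n), q = rep(NA_real_, n), z = bound_vals,
    w = numeric(n), dlf = numeric(n)
  )
  if (!any(fin)) {
    return(out)
  }
  link <- model$link
  m <- h_eta_d$h_over_d # already restricted to the finite-bound rows
  out$m[fin] <- m
  q <- std_normal_quantile_of(link, m)
  out$q[fin] <- q
  out$z[fin] <- h_eta_d$d[fin] * q
  out$w[fin] <- exp(link$log_pdf(m) - dnorm(q, log = TRUE))
  out$dlf[fin] <- link$dlog_pdf(m)
  out
}

# shared geometry: V = U Lambda, d, per-cluster Gram matrices etc.
prep_geometry <- function(model, gamma) {
  L <- cholesky_factor(gamma, R = model$R)
  V <- model$U %*% L
  d <- sqrt(rowSums(V^2) + 1)
  list(L = L, V = V, d = d)
}

# ---- continuous likelihood (log-density approximation) ---------------------

# solve (I + S) x = w for per-cluster R x R Gram matrices, vectorised.
# S is given columnwise: for R=1 a vector s11; for R=2 vectors s11,s12,s22.
cluster_gram <- function(V, cluster) {
  R <- ncol(V)
  if (R == 1L) {
    list(s11 = drop(rowsum(V[, 1L]^2, cluster)))
  } else {
    list(
      s11 = drop(rowsum(V[, 1L]^2, cluster)),
      s12 = drop(rowsum(V[, 1L] * V[, 2L], cluster)),
      s22 = drop(rowsum(V[, 2L]^2, cluster))
    )
  }
}

gram_logdet <- function(S, R) {
  if (R == 1L) {
    log1p(S$s11)
  } else {
    log((1 + S$s11) * (1 + S$s22) - S$s12^2)
  }
}

gram_solve <- function(S, w, R) {
  # w: ncl x R matrix; returns (I+S)^{-1} w
  if (R == 1L) {
    cbind(w[, 1L] / (1 + S$s11))
  } else {
    det <- (1 + S$s11) * (1 + S$s22) - S$s12^2
    cbind(
      ((1 + S$s22) * w[, 1L] - S$s12 * w[, 2L]) / det,
      (-S$s12 * w[, 1L] + (1 + S$s11) * w[, 2L]) / det
    )
  }
}

ll_continuous_engine <- function(model, theta, beta, gamma,
                                 want_score = FALSE) {
  geo <- prep_geometry(model, gamma)
  V <- geo$V
  d <- geo$d
  link <- model$link
  cl <- model$cluster
  h <- drop(model$A %*% theta)
  hp <- drop(model$Ad %*% theta)
  if (any(!is.finite(hp)) || any(hp <= 0)) {
    return(list(ll = -Inf))
  }
  eta <- if (ncol(model$X)) drop(model$X %*% beta) else numeric(model$n)
  m <- (h - eta) / d
  q <- std_normal_quantile_of(link, m)
  if (any(!is.finite(q))) {
    return(list(ll = -Inf))
  }
  z <- d * q
  S <- cluster_gram(V, cl)
  w_cl <- rowsum(V * z, cl) # ncl x R
  g_cl <- gram_solve(S, w_cl, model$R)
  logdet <- gram_logdet(S, model$R)
  quad_obs <- z^2 - q^2
  quad <- drop(rowsum(quad_obs, cl)) - rowSums(w_cl * g_cl)
  lf <- link$log_pdf(m)
  ll <- sum(-0.5 * logdet - 0.5 * quad) + sum(lf) + sum(log(hp))
  if (!want_score) {
    return(list(ll = ll))
  }

  # analytic score
  wj <- exp(lf - dnorm(q, log = TRUE)) # dz/d(h - eta) at fixed d
  dlf <- link$dlog_pdf(m)
  r <- rowSums(V * g_cl[cl, , drop = FALSE]) # (V g)_j
  u1 <- wj * (r - z * (1 - 1 / d^2)) + dlf / d
  g_theta <- drop(crossprod(model$A, u1)) + drop(crossprod(model$Ad, 1 / hp))
  g_beta <- if (ncol(model$X)) -drop(crossprod(model$X, u1)) else numeric(0)

  g_gamma <- numeric(model$M)
  idx <- 0L
  IS_inv_t <- function(tvec_cols, ck) {
    # rows of (I+S)^{-1} applied to per-cluster vectors t (ncl x R)
    gram_solve(S, tvec_cols, model$R)[, ck]
  }
  for (rk in seq_len(model$R)) {
    for (ck in seq_len(rk)) {
      idx <- idx + 1L
      dv <- model$U[, rk] # the single nonzero column (ck) of dV
      dd <- V[, ck] * dv / d
      dz <- dd * (q - wj * m)
      dm <- -m * dd / d
      # T1': -sum_i [ (I+S)^{-1} t_i ]_{ck} with t_i[c'] = sum_j dv V[,c']
      t_cl <- rowsum(dv * V, cl) # ncl x R
      g1 <- -sum(IS_inv_t(t_cl, ck))
      # T2'
      g2 <- -sum(z * (1 - 1 / d^2) * dz + z^2 * dd / d^3)
      # T3': sum_i g' dw - 0.5 g' dS g
      dw_cl <- rowsum(V * dz, cl)
      dw_cl[, ck] <- dw_cl[, ck] + drop(rowsum(dv * z, cl))
      gdSg <- 2 * g_cl[, ck] * rowSums(g_cl * t_cl)
      g3 <- sum(rowSums(g_cl * dw_cl)) - 0.5 * sum(gdSg)
      # T4'
      g4 <- sum(dlf * dm)
      g_gamma[idx] <- g1 + g2 + g3 + g4
    }
  }
  list(ll = ll, score = c(g_theta, g_beta, g_gamma))
}

# ---- censored likelihood (MVN rectangle via R-dim quadrature) --------------

# log of Phi(b) - Phi(a), elementwise, stable in both tails
log_pnorm_interval <- function(a, b) {
  out <- numeric(length(b))
  lo_inf <- !is.finite(a) & a < 0
  up_inf <- !is.finite(b) & b > 0
  both <- !lo_inf & !up_inf
  out[lo_inf & up_inf] <- 0
  i <- lo_inf & !up_inf
  out[i] <- pnorm(b[i], log.p = TRUE)
  i <- up_inf & !lo_inf
  out[i] <- pnorm(a[i], lower.tail = FALSE, log.p = TRUE)
  if (any(both)) {
    ab <- a[both]
    bb <- b[both]
    mid <- (ab + bb) / 2 < 0
    r <- numeric(length(ab))
    r[mid] <- logspace_sub(
      pnorm(bb[mid], log.p = TRUE),
      pnorm(ab[mid], log.p = TRUE)
    )
    r[!mid] <- logspace_sub(
      pnorm(ab[!mid], lower.tail = FALSE, log.p = TRUE),
      pnorm(bb[!mid], lower.tail = FALSE, log.p = TRUE)
    )
    out[both] <- r
  }
  out
}

# Adaptive quadrature geometry: mode and curvature of the per-cluster
# latent posterior density exp(-|s|^2/2) * prod_j P(zlo_j < Z_j <= zup_j | s),
# found by a damped Newton iteration vectorised over clusters. Shifting and
# scaling the Gauss-Hermite rule to this mode keeps the rule accurate when
# strong dependence moves the posterior far from the prior origin.
agq_geometry <- function(V, cl, ncl, R, zlo, zup) {
  rect_terms <- function(shift) {
    a <- zlo - shift
    b <- zup - shift
    lg <- log_pnorm_interval(a, b)
    wl <- ifelse(is.finite(a), exp(dnorm(a, log = TRUE) - lg), 0)
    wu <- ifelse(is.finite(b), exp(dnorm(b, log = TRUE) - lg), 0)
    wl[!is.finite(wl)] <- 0
    wu[!is.finite(wu)] <- 0
    e1 <- wl - wu
    t2 <- ifelse(is.finite(a), a * wl, 0) - ifelse(is.finite(b), b * wu, 0)
    list(e1 = e1, curv = t2 - e1^2)
  }
  colsum <- function(x) rowsum(x, cl)[, 1L]
  # Gaussian initial guess: mode of the posterior when each rectangle is
  # replaced by a point mass at its (finite) midpoint
  mid <- ifelse(is.finite(zlo) & is.finite(zup), (zlo + zup) / 2,
    ifelse(is.finite(zlo), zlo, zup)
  )
  mid <- pmin(pmax(mid, -6), 6)
  mu <- matrix(0, ncl, R)
  if (R == 1L) {
    mu[, 1L] <- colsum(V[, 1L] * mid) / (1 + colsum(V[, 1L]^2))
  }
  h11 <- h22 <- h12 <- NULL
  for (it in seq_len(12L)) {
    rt <- rect_terms(rowSums(V * mu[cl, , drop = FALSE]))
    if (R == 1L) {
      g1 <- -mu[, 1L] + colsum(V[, 1L] * rt$e1)
      h11 <- pmin(-1 + colsum(V[, 1L]^2 * rt$curv), -1e-4)
      step <- pmax(pmin(g1 / h11, 2), -2)
      mu[, 1L] <- mu[, 1L] - step
      if (max(abs(step)) < 1e-7) break
    } else {
      g1 <- -mu[, 1L] + colsum(V[, 1L] * rt$e1)
      g2 <- -mu[, 2L] + colsum(V[, 2L] * rt$e1)
      h11 <- pmin(-1 + colsum(V[, 1L]^2 * rt$curv), -1e-4)
      h22 <- pmin(-1 + colsum(V[, 2L]^2 * rt$curv), -1e-4)
      h12 <- colsum(V[, 1L] * V[, 2L] * rt$curv)
      det <- h11 * h22 - h12^2
      h12[det <= 0] <- 0 # fall back to a diagonal step if indefinite
      det <- h11 * h22 - h12^2
      s1 <- pmax(pmin((g1 * h22 - g2 * h12) / det, 2), -2)
      s2 <- pmax(pmin((g2 * h11 - g1 * h12) / det, 2), -2)
      mu[, 1L] <- mu[, 1L] - s1
      mu[, 2L] <- mu[, 2L] - s2
      mu <- pmax(pmin(mu, 8), -8)
      if (max(abs(s1), abs(s2)) < 1e-7) break
    }
    if (R == 1L) mu <- pmax(pmin(mu, 8), -8)
  }
  if (R == 1L) {
    sig <- 1 / sqrt(-h11)
    list(mu = mu, C11 = sig, logdet = log(sig))
  } else {
    # C C' = (-H)^{-1} with C lower triangular
    det <- h11 * h22 - h12^2
    b11 <- -h22 / det
    b21 <- h12 / det
    b22 <- -h11 / det
    C11 <- sqrt(b11)
    C21 <- b21 / C11
    C22 <- sqrt(pmax(b22 - C21^2, 1e-8))
    list(
      mu = mu, C11 = C11, C21 = C21, C22 = C22,
      logdet = log(C11) + log(C22)
    )
  }
}

# Build the per-observation node shifts and per-cluster log-weight
# corrections for the adapted rule: s_ik = mu_i + C_i t_k with standard
# product-rule nodes t_k, so the integral of phi(s) g(s) becomes
# sum_k w_k exp((|t_k|^2 - |s_ik|^2)/2 + log|C_i|) g(s_ik).
agq_nodes <- function(gq, gh, V, cl, ncl, R) {
  K <- nrow(gh$smat)
  t1 <- gh$smat[, 1L]
  if (R == 1L) {
    s1 <- matrix(gq$mu[, 1L], ncl, K) + gq$C11 %o% t1
    lwc <- matrix(gh$lw, ncl, K, byrow = TRUE) +
      (matrix(t1^2, ncl, K, byrow = TRUE) - s1^2) / 2 + log(gq$C11)
    list(
      vs = V[, 1L] * s1[cl, , drop = FALSE], lwc = lwc,
      smat_obs = list(s1[cl, , drop = FALSE])
    )
  } else {
    t2 <- gh$smat[, 2L]
    s1 <- matrix(gq$mu[, 1L], ncl, K) + gq$C11 %o% t1
    s2 <- matrix(gq$mu[, 2L], ncl, K) + gq$C21 %o% t1 + gq$C22 %o% t2
    lwc <- matrix(gh$lw, ncl, K, byrow = TRUE) +
      (matrix(t1^2 + t2^2, ncl, K, byrow = TRUE) - s1^2 - s2^2) / 2 +
      gq$logdet
    s1o <- s1[cl, , drop = FALSE]
    s2o <- s2[cl, , drop = FALSE]
    list(
      vs = V[, 1L] * s1o + V[, 2L] * s2o, lwc = lwc,
      smat_obs = list(s1o, s2o)
    )
  }
}

ll_censored_engine <- function(model, theta, beta, gamma,
                               want_score = FALSE) {
  geo <- prep_geometry(model, gamma)
  V <- geo$V
  d <- geo$d
  cl <- model$cluster
  eta <- if (ncol(model$X)) drop(model$X %*% beta) else numeric(model$n)
  hd <- function(A, fin) {
    list(
      h_over_d = (drop(A %*% theta)[fin] - eta[fin]) / d[fin],
      d = d
    )
  }
  lo_t <- transform_bound(
    model, model$A_lo, model$lo, model$fin_lo,
    hd(model$A_lo, model$fin_lo)
  )
  up_t <- transform_bound(
    model, model$A_up, model$up, model$fin_up,
    hd(model$A_up, model$fin_up)
  )
  if (any(up_t$z < lo_t$z)) {
    return(list(ll = -Inf))
  }
  if (all(abs(V) < 1e-14)) {
    # independence: the latent factor integrates out trivially
    K <- 1L
    vs <- matrix(0, model$n, 1L)
    lwc <- matrix(0, model$ncl, 1L)
    smat_obs <- rep(list(matrix(0, model$n, 1L)), model$R)
  } else {
    gq <- agq_geometry(V, cl, model$ncl, model$R, lo_t$z, up_t$z)
    nd <- agq_nodes(gq, model$gh, V, cl, model$ncl, model$R)
    K <- nrow(model$gh$smat)
    vs <- nd$vs
    lwc <- nd$lwc
    smat_obs <- nd$smat_obs
  }
  am <- lo_t$z - vs # recycled bounds minus shift
  bm <- up_t$z - vs
  lg <- matrix(
    log_pnorm_interval(as.numeric(am), as.numeric(bm)),
    model$n, K
  )
  cp <- rowsum(lg, cl) + lwc # ncl x K, node weights included
  ll_i <- logsumexp_rows(cp)
  if (any(ll_i < log(1e-300))) {
    bad <- which(ll_i < log(1e-300))
    stop(
      "likelihood underflow (probability < 1e-300) for cluster(s) ",
      paste(bad, collapse = ", "), call. = FALSE
    )
  }
  ll <- sum(ll_i)
  if (!want_score) {
    return(list(ll = ll))
  }

  # posterior node weights per observation: Omega_{jk}
  Omega <- exp(cp - ll_i)[cl, , drop = FALSE]
  Wu <- matrix(0, model$n, K)
  Wl <- matrix(0, model$n, K)
  if (any(model$fin_up)) {
    i <- model$fin_up
    Wu[i, ] <- exp(dnorm(bm[i, , drop = FALSE], log = TRUE) -
      lg[i, , drop = FALSE])
  }
  if (any(model$fin_lo)) {
    i <- model$fin_lo
    Wl[i, ] <- exp(dnorm(am[i, , drop = FALSE], log = TRUE) -
      lg[i, , drop = FALSE])
  }
  # nodes where the rectangle probability underflows carry zero posterior
  # weight; make sure they do not poison the gradient with 0 * Inf
  Wu[!is.finite(Wu)] <- 0
  Wl[!is.finite(Wl)] <- 0
  ru <- rowSums(Omega * Wu)
  rl <- rowSums(Omega * Wl)
  g_theta <- drop(crossprod(model$A_up, up_t$w * ru)) -
    drop(crossprod(model$A_lo, lo_t$w * rl))
  g_beta <- if (ncol(model$X)) {
    -drop(crossprod(model$X, up_t$w * ru - lo_t$w * rl))
  } else {
    numeric(0)
  }

  g_gamma <- numeric(model$M)
  idx <- 0L
  q_up <- ifelse(model$fin_up, up_t$q, 0)
  q_lo <- ifelse(model$fin_lo, lo_t$q, 0)
  m_up <- ifelse(model$fin_up, up_t$m, 0)
  m_lo <- ifelse(model$fin_lo, lo_t$m, 0)
  for (rk in seq_len(model$R)) {
    for (ck in seq_len(rk)) {
      idx <- idx + 1L
      dv <- model$U[, rk]
      dd <- V[, ck] * dv / d
      cu <- dd * (q_up - up_t$w * m_up)
      clw <- dd * (q_lo - lo_t$w * m_lo)
      # shift term: - dv_j' s_k acts on both bounds
      Tj <- rowSums(Omega * (Wu - Wl) * smat_obs[[ck]])
      g_gamma[idx] <- sum(cu * ru) - sum(clw * rl) - sum(dv * Tj)
    }
  }
  list(ll = ll, score = c(g_theta, g_beta, g_gamma))
}

# ---- exported likelihood surface -------------------------------------------

#' Cluster log-likelihoods of the marginal transformation model
#'
#' `loglik_continuous()` evaluates the log-density approximation to the
#' likelihood for exactly observed continuous responses;
#' `score_continuous()` its analytic gradient with respect to
#' \eqn{(\vartheta, \beta, \gamma)}. `loglik_censored()` evaluates the
#' exact likelihood for interval-censored / discrete responses through
#' dimension-reduced multivariate-normal rectangle probabilities, and
#' `score_censored()` the gradient obtained by differentiating the
#' quadrature representation. All functions sum over the clusters present
#' in `cluster`.
#'
#' @param y Numeric responses (continuous case).
#' @param lower,upper Censoring bounds (\eqn{\pm}`Inf` allowed) for the
#'   censored case.
#' @param X Fixed-effect design matrix or `NULL`.
#' @param U Random-effect design matrix.
#' @param cluster Cluster identifiers (any type; coerced to integers).
#' @param theta,beta,gamma Parameter blocks.
#' @param basis A [basis_spec()].
#' @param link A [link_family()] or name.
#' @param gh_nodes Number of Gauss-Hermite nodes per latent dimension.
#' @return A scalar log-likelihood, or for the score functions a numeric
#'   gradient of length `length(theta) + length(beta) + length(gamma)`.
#' @export
loglik_continuous <- function(y, X, U, cluster, theta, beta, gamma,
                              basis, link) {
  m <- build_model(y, y, rep(TRUE, length(y)), X, U, cluster,
    link, basis,
    strata = NULL
  )
  ll_continuous_engine(m, theta, beta, gamma)$ll
}

#' @rdname loglik_continuous
#' @export
score_continuous <- function(y, X, U, cluster, theta, beta, gamma,
                             basis, link) {
  m <- build_model(y, y, rep(TRUE, length(y)), X, U, cluster,
    link, basis,
    strata = NULL
  )
  ll_continuous_engine(m, theta, beta, gamma, want_score = TRUE)$score
}

#' @rdname loglik_continuous
#' @export
loglik_censored <- function(lower, upper, X, U, cluster, theta, beta,
                            gamma, basis, link, gh_nodes = 40L) {
  m <- build_model(lower, upper, rep(FALSE, length(lower)), X, U, cluster,
    link, basis,
    strata = NULL, gh_nodes = gh_nodes
  )
  ll_censored_engine(m, theta, beta, gamma)$ll
}

#' @rdname loglik_continuous
#' @export
score_censored <- function(lower, upper, X, U, cluster, theta, beta,
                           gamma, basis, link, gh_nodes = 40L) {
  m <- build_model(lower, upper, rep(FALSE, length(lower)), X, U, cluster,
    link, basis,
    strata = NULL, gh_nodes = gh_nodes
  )
  ll_censored_engine(m, theta, beta, gamma, want_score = TRUE)$score
}

#' Multivariate normal rectangle probability with structured covariance
#'
#' Computes \eqn{P(l < Z \le u)} for \eqn{Z \sim N(0, \Sigma(\gamma))}
#' with \eqn{\Sigma = U\Lambda\Lambda^\top U^\top + I}. The
#' \eqn{N_i}-dimensional integral is reduced to an \eqn{R}-dimensional one
#' by conditioning on the latent factor \eqn{s \sim N(0, I_R)}: given
#' \eqn{s}, the coordinates are independent with unit variance, so the
#' integrand is a product of univariate normal rectangle probabilities,
#' integrated by Gauss-Hermite quadrature.
#'
#' @param lower,upper Numeric bound vectors (\eqn{\pm}`Inf` allowed).
#' @param U Random-effect design matrix for the cluster.
#' @param gamma Covariance parameters.
#' @param gh_nodes Nodes per latent dimension.
#' @param check If `TRUE`, re-evaluate with a doubled rule and signal an
#'   error when the two disagree beyond `tol`.
#' @param tol Rule-doubling tolerance.
#' @return A probability in \[0, 1\].
#' @examples
#' mvn_rectangle(rep(-1, 3), rep(1, 3), matrix(1, 3, 1), gamma = 0)
#' pnorm(1) - pnorm(-1) # cubed above
#' @export
mvn_rectangle <- function(lower, upper, U, gamma, gh_nodes = 40L,
                          check = TRUE, tol = 1e-8) {
  stopifnot(all(lower <= upper))
  U <- as.matrix(U)
  L <- cholesky_factor(gamma, R = ncol(U))
  V <- U %*% L
  p <- exp(mvn_rect_log(lower, upper, V, gh_rule(ncol(U), gh_nodes)))
  if (check) {
    p2 <- exp(mvn_rect_log(lower, upper, V, gh_rule(ncol(U), 2L * gh_nodes)))
    if (abs(p - p2) > max(tol, 1e-6 * p)) {
      stop("quadrature did not converge: rule-doubling discrepancy ",
        signif(abs(p - p2), 3), call. = FALSE
      )
    }
  }
  min(max(p, 0), 1)
}

mvn_rect_log <- function(zlo, zup, V, gh) {
  n <- length(zlo)
  if (all(abs(V) < 1e-14)) {
    return(sum(log_pnorm_interval(zlo, zup)))
  }
  cl <- rep(1L, n)
  gq <- agq_geometry(V, cl, 1L, ncol(V), zlo, zup)
  nd <- agq_nodes(gq, gh, V, cl, 1L, ncol(V))
  lg <- matrix(
    log_pnorm_interval(
      as.numeric(zlo - nd$vs),
      as.numeric(zup - nd$vs)
    ),
    n, nrow(gh$smat)
  )
  logsumexp_rows(colSums(lg) + nd$lwc)[1L]
}
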