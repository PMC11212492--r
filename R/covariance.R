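#' Structured latent covariance of the Gaussian copula
#'
#' The latent Gaussian vector of a cluster with random-effect design
#' \eqn{U_i} (an \eqn{N_i \times R} matrix: a column of ones for a random
#' intercept, columns \eqn{(1, t_{ij})} for intercept plus slope) has
#' covariance \deqn{\Sigma_i(\gamma) = U_i \Lambda(\gamma)
#' \Lambda(\gamma)^\top U_i^\top + I_{N_i},} where \eqn{\Lambda(\gamma)} is
#' an unstructured lower-triangular Cholesky factor filled row-wise from
#' \eqn{\gamma} (\eqn{R(R+1)/2} entries, nonnegative diagonal).
#'
#' `cholesky_factor()` builds \eqn{\Lambda(\gamma)}; `sigma_build()` the
#' full \eqn{\Sigma_i}; `scale_diag()` the diagonal scaling matrix
#' \eqn{D_i = \mathrm{diag}(\Sigma_i)^{1/2}}; and `marginal_scale()` the
#' per-observation standard deviation \eqn{\sqrt{u^\top \Lambda
#' \Lambda^\top u + 1}} by which fixed effects are shrunk on the marginal
#' scale.
#'
#' @param gamma Numeric vector of length \eqn{R(R+1)/2} filling the
#'   lower triangle of \eqn{\Lambda} row-wise (\eqn{\gamma_1};
#'   \eqn{\gamma_2, \gamma_3}; ...).
#' @param R Random-effect dimension.
#' @param U Numeric matrix (\eqn{N_i \times R}) of random-effect
#'   covariates for one cluster.
#' @param u Numeric vector of length \eqn{R}, a single random-effect
#'   covariate row.
#' @return `cholesky_factor()`: an \eqn{R \times R} lower-triangular
#'   matrix. `sigma_build()`: an \eqn{N_i \times N_i} covariance matrix.
#'   `scale_diag()`: an \eqn{N_i \times N_i} diagonal matrix.
#'   `marginal_scale()`: a scalar \eqn{\ge 1}.
#' @examples
#' cholesky_factor(c(1, -0.3, 0.7), R = 2)
#' sigma_build(matrix(1, 2, 1), gamma = 1) # compound symmetry, gamma1 = 1
#' marginal_scale(1, gamma = 3)^2 # 10
#' @export
cholesky_factor <- function(gamma, R = n_raneff_dim(gamma)) {
  M <- R * (R + 1L) / 2L
  if (length(gamma) != M) {
    stop("length(gamma) must be R(R+1)/2 = ", M, ".", call. = FALSE)
  }
  L <- matrix(0, R, R)
  L[upper.tri(L, diag = TRUE)] <- 0
  L[lower.tri(L, diag = TRUE)] <- 0
  idx <- 1L
  for (r in seq_len(R)) {
    L[r, seq_len(r)] <- gamma[idx:(idx + r - 1L)]
    idx <- idx + r
  }
  if (any(diag(L) < 0)) {
    stop("diagonal entries of the Cholesky factor must be nonnegative.",
      call. = FALSE
    )
  }
  L
}

n_raneff_dim <- function(gamma) {
  R <- (sqrt(8 * length(gamma) + 1) - 1) / 2
  if (R != round(R)) {
    stop("length(gamma) is not a triangular number R(R+1)/2.",
      call. = FALSE
    )
  }
  as.integer(R)
}

#' @rdname cholesky_factor
#' @export
sigma_build <- function(U, gamma) {
  U <- as.matrix(U)
  L <- cholesky_factor(gamma, R = ncol(U))
  V <- U %*% L
  tcrossprod(V) + diag(nrow(U))
}

#' @rdname cholesky_factor
#' @export
scale_diag <- function(U, gamma) {
  U <- as.matrix(U)
  L <- cholesky_factor(gamma, R = ncol(U))
  diag(sqrt(rowSums((U %*% L)^2) + 1), nrow = nrow(U))
}

#' @rdname cholesky_factor
#' @export
marginal_scale <- function(u, gamma) {
  u <- as.numeric(u)
  L <- cholesky_factor(gamma, R = length(u))
  sqrt(sum((crossprod(L, u))^2) + 1)
}

# per-observation latent scales sqrt(u_ij' LL' u_ij + 1), vectorised over
# the rows of U
obs_scales <- function(U, L) {
  sqrt(rowSums((U %*% L)^2) + 1)
}
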