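#' Baseline transformation bases
#'
#' The monotone baseline transformation is parameterised as
#' \eqn{h(y) = a(y)^\top \vartheta} with basis \eqn{a}. Available bases:
#'
#' * `bernstein`: monotone polynomial in Bernstein form of degree `order` on
#'   the finite interval `support`; \eqn{P = order + 1} coefficients,
#'   monotone iff the coefficient sequence is nondecreasing.
#' * `linear`: \eqn{a(y) = (y, -1)^\top}; with \eqn{\vartheta =
#'   (1/\sigma, \alpha/\sigma)} this is the normal-linear-model
#'   transformation \eqn{(y - \alpha)/\sigma}.
#' * `loglinear`: \eqn{a(y) = (1, \log y)^\top} on positive supports
#'   (Weibull-type log-cumulative hazards).
#' * `binary_intercept`: a single cut point \eqn{h(0) = \alpha},
#'   \eqn{h(1) = \infty}, for binary responses.
#' * `ordinal_steps`: one monotone step parameter per interior cut point of
#'   a `n_levels`-level ordinal response (experimental).
#'
#' @param kind Basis kind, see above.
#' @param order Bernstein degree (ignored otherwise).
#' @param support Length-2 numeric, the response interval the basis lives
#'   on. Required for `bernstein`; for `loglinear` it must sit inside
#'   \eqn{(0, \infty)}.
#' @param n_levels Number of response levels for `ordinal_steps`.
#' @return An object of class `basis_spec` with elements `kind`, `order`,
#'   `support`, `n_param`.
#' @examples
#' bs <- basis_spec("bernstein", order = 6, support = c(0, 30))
#' rowSums(basis_row(bs, c(1, 17))) # partition of unity
#' @export
basis_spec <- function(kind = c(
                         "bernstein", "linear", "loglinear",
                         "binary_intercept", "ordinal_steps"
                       ),
                       order = 6L, support = NULL, n_levels = NULL) {
  kind <- match.arg(kind)
  if (!is.null(support)) {
    if (length(support) != 2L || !all(is.finite(support)) ||
      support[1L] >= support[2L]) {
      stop("`support` must be a finite interval c(lo, hi) with lo < hi.",
        call. = FALSE
      )
    }
  }
  n_param <- switch(kind,
    bernstein = {
      if (is.null(support)) {
        stop("a bernstein basis needs a finite `support`.", call. = FALSE)
      }
      order <- as.integer(order)
      stopifnot(order >= 0L)
      order + 1L
    },
    linear = 2L,
    loglinear = {
      if (!is.null(support) && support[1L] <= 0) {
        stop("a loglinear basis needs support within (0, Inf).",
          call. = FALSE
        )
      }
      2L
    },
    binary_intercept = 1L,
    ordinal_steps = {
      if (is.null(n_levels) || n_levels < 2L) {
        stop("ordinal_steps needs `n_levels` >= 2.", call. = FALSE)
      }
      as.integer(n_levels) - 1L
    }
  )
  structure(
    list(
      kind = kind, order = if (kind == "bernstein") order else NA_integer_,
      support = support, n_param = n_param,
      n_levels = if (kind == "ordinal_steps") as.integer(n_levels) else NULL
    ),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec>", x$kind,
    if (x$kind == "bernstein") paste0("(order ", x$order, ")") else "",
    if (!is.null(x$support)) {
      paste0("on [", x$support[1L], ", ", x$support[2L], "]")
    } else {
      ""
    }, "\n"
  )
  invisible(x)
}

# Bernstein polynomials B_{p,M}(u), p = 0..M, as an n x (M+1) matrix
bernstein_matrix <- function(u, order) {
  p <- 0:order
  out <- outer(u, p, function(uu, pp) {
    exp(lchoose(order, pp) + pp * log(pmax(uu, 0)) +
      (order - pp) * log(pmax(1 - uu, 0)))
  })
  # 0^0 conventions at the endpoints
  out[u == 0, ] <- rep(c(1, numeric(order)), each = sum(u == 0))
  out[u == 1, ] <- rep(c(numeric(order), 1), each = sum(u == 1))
  out
}

clamp_to_support <- function(spec, y) {
  fin <- is.finite(y)
  lo <- spec$support[1L]
  hi <- spec$support[2L]
  n_out <- sum(fin & (y < lo | y > hi))
  if (n_out > 0L) {
    rlang::inform(
      paste0(
        n_out, " response value(s) outside the basis support were clamped ",
        "to [", signif(lo, 6), ", ", signif(hi, 6), "]."
      ),
      class = "martram_clamp"
    )
  }
  y[fin] <- pmin(pmax(y[fin], lo), hi)
  y
}

#' Evaluate basis rows and their derivatives
#'
#' `basis_row()` evaluates \eqn{a(y)^\top} for each element of `y`,
#' returning an \eqn{n \times P} matrix; `basis_deriv_row()` returns the
#' elementwise derivative \eqn{a'(y)^\top} (continuous bases only).
#' Values outside the support of a Bernstein basis are clamped to the
#' nearest boundary (with a message). Infinite `y` are allowed in
#' `basis_row()` and produce rows that evaluate \eqn{h(\pm\infty) =
#' \pm\infty} when combined with coefficients; they are returned as the
#' boundary row with an attribute-free convention handled by the
#' likelihood layer.
#'
#' @param spec A [basis_spec()].
#' @param y Numeric vector of response values (cut-point indices for
#'   discrete bases).
#' @return Numeric matrix with `length(y)` rows and `spec$n_param` columns.
#' @export
basis_row <- function(spec, y) {
  switch(spec$kind,
    bernstein = {
      y <- clamp_to_support(spec, y)
      u <- (y - spec$support[1L]) / diff(spec$support)
      u[!is.finite(y)] <- 0.5 # placeholder; infinite bounds bypass h
      bernstein_matrix(u, spec$order)
    },
    linear = cbind(y, -1),
    loglinear = cbind(1, log(y)),
    binary_intercept = matrix(1, nrow = length(y), ncol = 1L),
    ordinal_steps = {
      k <- as.integer(y)
      if (any(k < 1L | k > spec$n_param, na.rm = TRUE)) {
        stop("ordinal cut-point index out of range.", call. = FALSE)
      }
      m <- matrix(0, nrow = length(y), ncol = spec$n_param)
      m[cbind(seq_along(k), k)] <- 1
      m
    }
  )
}

#' @rdname basis_row
#' @export
basis_deriv_row <- function(spec, y) {
  switch(spec$kind,
    bernstein = {
      y <- clamp_to_support(spec, y)
      u <- (y - spec$support[1L]) / diff(spec$support)
      M <- spec$order
      if (M == 0L) {
        return(matrix(0, length(y), 1L))
      }
      inner <- bernstein_matrix(u, M - 1L)
      (cbind(-inner, 0) + cbind(0, inner)) * (M / diff(spec$support))
    },
    linear = cbind(rep(1, length(y)), 0),
    loglinear = cbind(0, 1 / y),
    stop("the density of a discrete-basis model is undefined; ",
      "basis_deriv_row() applies to continuous bases only.",
      call. = FALSE
    )
  )
}

#' Monotonicity constraints on transformation coefficients
#'
#' Returns the matrix `C` of the linear inequality system
#' \eqn{C\vartheta \ge 0} that makes \eqn{h(y) = a(y)^\top\vartheta}
#' monotone nondecreasing: first differences for `bernstein` and
#' `ordinal_steps`, positivity of the slope (resp. log-slope) coefficient
#' for `linear` and `loglinear`, and an empty system for the free scalar
#' `binary_intercept`.
#'
#' @param spec A [basis_spec()].
#' @return A numeric matrix with `spec$n_param` columns (possibly 0 rows).
#' @export
monotonicity_constraints <- function(spec) {
  P <- spec$n_param
  switch(spec$kind,
    bernstein = ,
    ordinal_steps = {
      if (P < 2L) {
        return(matrix(0, 0L, P))
      }
      diff(diag(P))
    },
    linear = matrix(c(1, 0), 1L, 2L),
    loglinear = matrix(c(0, 1), 1L, 2L),
    binary_intercept = matrix(0, 0L, 1L)
  )
}
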