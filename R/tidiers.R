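#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted marginal transformation model
#'
#' One row per parameter with standard errors from the observed Fisher
#' information. Fixed-effect rows additionally carry the shrunken
#' marginal effect \eqn{\mu = \beta/\sqrt{u^\top\Lambda\Lambda^\top u +
#' 1}} at the cluster-intercept row `u = (1, 0, ...)`.
#'
#' @param x An `mtram_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block` (`"transformation"`,
#'   `"fixed"`, `"covariance"`), `estimate`, `std.error`, `marginal`.
#' @export
tidy.mtram_fit <- function(x, ...) {
  V <- x$vcov %||% vcov_observed(x)
  sp <- x$spec
  Ptot <- sp$P * sp$S
  block <- c(
    rep("transformation", Ptot), rep("fixed", sp$Q),
    rep("covariance", sp$M)
  )
  s <- marginal_scale(c(1, numeric(sp$R - 1L)), x$gamma)
  tibble::tibble(
    term = names(x$par),
    block = block,
    estimate = unname(x$par),
    std.error = sqrt(pmax(diag(V), 0)),
    marginal = ifelse(block == "fixed", unname(x$par) / s, NA_real_)
  )
}

#' Glance at a fitted marginal transformation model
#'
#' @param x An `mtram_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `npar`, `nobs`, `n_clusters`,
#'   `link`, `basis`, `convergence` (optimizer code), `grad_norm`.
#' @export
glance.mtram_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    npar = length(x$par),
    nobs = x$model$n,
    n_clusters = x$model$ncl,
    link = x$spec$link$name,
    basis = x$spec$basis$kind,
    convergence = x$convergence$code,
    grad_norm = x$convergence$projected_gradient_norm
  )
}

#' Plot marginal distribution functions of a fitted model
#'
#' `autoplot()` draws the closed-form marginal CDF at one or more
#' covariate configurations; `plot_study()` displays simulation-study
#' metrics across latent correlation scales.
#'
#' @param object An `mtram_fit`.
#' @param newdata Optional data frame of covariate rows (one curve each);
#'   defaults to the baseline configuration `x = 0`.
#' @param n_grid Number of grid points across the basis support.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtram_fit <- function(object, newdata = NULL, n_grid = 200L,
                               ...) {
  sp <- object$spec
  if (is.null(sp$basis$support)) {
    stop("autoplot() needs a continuous basis with finite support.",
      call. = FALSE
    )
  }
  grid <- seq(sp$basis$support[1L], sp$basis$support[2L],
    length.out = n_grid
  )
  if (is.null(newdata)) {
    newdata <- as.data.frame(matrix(0, 1L, sp$Q,
      dimnames = list(NULL, sp$covariates)
    ))
  }
  curves <- purrr::map_dfr(seq_len(nrow(newdata)), function(i) {
    x <- as.numeric(newdata[i, sp$covariates, drop = TRUE])
    cdf <- marginal_cdf(object, grid, x = x)
    cdf$configuration <- paste0(
      sp$covariates, "=", signif(x, 3),
      collapse = ", "
    )
    cdf
  })
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$y, y = .data$cdf,
    colour = .data$configuration
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "response", y = "marginal P(Y ≤ y | x)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mtram_fit
#' @param study An `mtram_study` tibble from [run_study()].
#' @export
plot_study <- function(study, ...) {
  long <- tidyr::pivot_longer(study, c("mse", "ci_width", "coverage"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$gamma1, y = .data$value,
    colour = .data$effect, linetype = .data$estimator
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(gamma[1]), y = NULL) +
    ggplot2::theme_minimal()
}
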