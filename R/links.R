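#' Inverse link families
#'
#' A link family fixes the scale on which covariate effects are linear in a
#' transformation model \eqn{P(Y \le y \mid x) = F(h(y) - x^\top\beta)}.
#' The inverse link \eqn{F} is the CDF of a continuous distribution with
#' log-concave density \eqn{f}:
#'
#' * `probit`: standard normal; effects shift the conditional mean of
#'   \eqn{h(Y)}.
#' * `logit`: standard logistic; effects are log-odds ratios.
#' * `cloglog`: minimum extreme value (Gompertz); effects are log-hazard
#'   ratios.
#' * `loglog`: maximum extreme value (Gumbel); effects are log-reverse-time
#'   hazard ratios.
#'
#' All families carry log-scale CDF and survivor functions so that tail
#' probabilities (needed deep in the tails of the latent Gaussian transform)
#' are evaluated without underflow.
#'
#' @param name One of `"probit"`, `"logit"`, `"cloglog"`, `"loglog"`.
#' @return An object of class `link_family`: a list of vectorised functions
#'   `cdf`, `pdf`, `quantile`, `log_cdf`, `log_sf`, `log_pdf`, and
#'   `dlog_pdf` (the derivative \eqn{f'/f} of the log-density), plus the
#'   family `name` and the `scale_name` used to label effect estimates.
#' @examples
#' lf <- link_family("logit")
#' lf$cdf(0) # 0.5
#' lf$quantile(lf$cdf(1.3)) # 1.3
#' @export
link_family <- function(name = c("probit", "logit", "cloglog", "loglog")) {
  name <- match.arg(name)
  fam <- switch(name,
    probit = list(
      cdf = pnorm,
      pdf = dnorm,
      quantile = qnorm,
      log_cdf = function(z) pnorm(z, log.p = TRUE),
      log_sf = function(z) pnorm(z, lower.tail = FALSE, log.p = TRUE),
      log_pdf = function(z) dnorm(z, log = TRUE),
      dlog_pdf = function(z) -z,
      scale_name = "conditional mean shift"
    ),
    logit = list(
      cdf = plogis,
      pdf = dlogis,
      quantile = qlogis,
      log_cdf = function(z) plogis(z, log.p = TRUE),
      log_sf = function(z) plogis(z, lower.tail = FALSE, log.p = TRUE),
      log_pdf = function(z) dlogis(z, log = TRUE),
      dlog_pdf = function(z) 1 - 2 * plogis(z),
      scale_name = "log-odds ratio"
    ),
    cloglog = list(
      # F(z) = 1 - exp(-exp(z)), minimum extreme value
      cdf = function(z) -expm1(-exp(z)),
      pdf = function(z) exp(z - exp(z)),
      quantile = function(p) log(-log1p(-p)),
      log_cdf = function(z) log1mexp(-exp(z)),
      log_sf = function(z) -exp(z),
      log_pdf = function(z) z - exp(z),
      dlog_pdf = function(z) 1 - exp(z),
      scale_name = "log-hazard ratio"
    ),
    loglog = list(
      # F(z) = exp(-exp(-z)), maximum extreme value
      cdf = function(z) exp(-exp(-z)),
      pdf = function(z) exp(-z - exp(-z)),
      quantile = function(p) -log(-log(p)),
      log_cdf = function(z) -exp(-z),
      log_sf = function(z) log1mexp(-exp(-z)),
      log_pdf = function(z) -z - exp(-z),
      dlog_pdf = function(z) exp(-z) - 1,
      scale_name = "log-reverse-time hazard ratio"
    )
  )
  fam$name <- name
  structure(fam, class = "link_family")
}

#' @export
print.link_family <- function(x, ...) {
  cat("<link_family>", x$name, "-", x$scale_name, "\n")
  invisible(x)
}

as_link <- function(link) {
  if (inherits(link, "link_family")) link else link_family(link)
}

#' Evaluate an inverse link, its density, or its quantile
#'
#' Thin vectorised accessors for a [link_family()]. `inverse_link()` maps a
#' linear-predictor value to a probability, `link_density()` is its
#' derivative, and `link_quantile()` the inverse map.
#'
#' @param family A `link_family` object or a family name.
#' @param z Numeric vector of linear-predictor values.
#' @param p Numeric vector of probabilities in (0, 1).
#' @return Numeric vector.
#' @examples
#' inverse_link("cloglog", 0) # 1 - exp(-1)
#' link_density("probit", 0) # 1 / sqrt(2 * pi)
#' link_quantile("logit", 0.5) # 0
#' @export
inverse_link <- function(family, z) {
  stopifnot(all(is.finite(z)))
  as_link(family)$cdf(z)
}

#' @rdname inverse_link
#' @export
link_density <- function(family, z) {
  stopifnot(all(is.finite(z)))
  as_link(family)$pdf(z)
}

#' @rdname inverse_link
#' @export
link_quantile <- function(family, p) {
  if (any(p <= 0 | p >= 1)) {
    stop("link_quantile() needs probabilities strictly inside (0, 1); ",
      "represent boundary cases through infinite censoring bounds.",
      call. = FALSE
    )
  }
  as_link(family)$quantile(p)
}

# standard-normal quantile of F(m), computed through log-probabilities so
# that the composition qnorm(F(m)) stays accurate far in both tails
std_normal_quantile_of <- function(link, m) {
  out <- m
  fin <- is.finite(m)
  if (any(fin)) {
    mm <- m[fin]
    lp <- link$log_cdf(mm)
    ls <- link$log_sf(mm)
    low <- lp < log(0.5)
    q <- numeric(length(mm))
    q[low] <- qnorm(lp[low], log.p = TRUE)
    q[!low] <- qnorm(ls[!low], lower.tail = FALSE, log.p = TRUE)
    out[fin] <- q
  }
  out # +-Inf map to +-Inf
}
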