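#' Simulation study of marginal-effect inference
#'
#' Replicates the empirical evaluation of marginal transformation model
#' inference: for each scenario (a latent correlation scale `gamma1`
#' crossed with an estimator), datasets are simulated with
#' [simulate_clustered()], optionally dichotomised at the pooled median,
#' fitted, and the scaled marginal effects \eqn{\hat\mu_p =
#' \hat\beta_p/\sqrt{1+\hat\gamma_1^2}} recorded together with
#' confidence intervals obtained from `B_ci` draws of the asymptotic
#' joint normal of \eqn{(\hat\beta, \hat\gamma_1)}. Reported metrics per
#' scenario and effect: mean squared error against the true
#' \eqn{\mu_p = (1+\gamma_1^2)^{-1/2}\beta_p}, mean interval width, and
#' empirical coverage.
#'
#' Replicate `r` of every scenario uses seed `seed + r`, so any single
#' replicate can be rerun in isolation; failed replicates are counted and
#' a scenario aborts if more than `max_fail_rate` of its replicates fail.
#'
#' @param gamma1 Numeric vector of latent correlation scales.
#' @param estimator `"continuous"` (logit link, Bernstein transformation)
#'   and/or `"binary"` (single-intercept logit model on the median split).
#' @param n_reps Replicates per scenario.
#' @param n_clusters,cluster_size,beta,baseline_df DGP settings, see
#'   [simulate_clustered()].
#' @param order Bernstein degree of the continuous estimator.
#' @param B_ci Draws for the simulation-based confidence intervals.
#' @param level Confidence level.
#' @param seed Base seed.
#' @param max_fail_rate Abort threshold for per-scenario failures.
#' @return A tibble of class `mtram_study` with columns `estimator`,
#'   `gamma1`, `effect`, `true_mu`, `mse`, `ci_width`, `coverage`,
#'   their Monte-Carlo standard errors (`mse_se`, `ci_width_se`,
#'   `coverage_se`), `n_reps` (successful replicates), `n_failed`.
#' @export
run_study <- function(gamma1 = c(0, 0.5, 1, 1.5, 2, 3),
                      estimator = c("continuous", "binary"),
                      n_reps = 1000L, n_clusters = 100L, cluster_size = 5L,
                      beta = c(0, 1, 2), baseline_df = 9, order = 6L,
                      B_ci = 10000L, level = 0.95, seed = 1L,
                      max_fail_rate = 0.05) {
  estimator <- match.arg(estimator, several.ok = TRUE)
  scen <- expand.grid(
    gamma1 = gamma1, estimator = estimator,
    stringsAsFactors = FALSE
  )
  res <- purrr::pmap(scen, function(gamma1, estimator) {
    run_scenario(
      gamma1 = gamma1, estimator = estimator, n_reps = n_reps,
      n_clusters = n_clusters, cluster_size = cluster_size, beta = beta,
      baseline_df = baseline_df, order = order, B_ci = B_ci,
      level = level, seed = seed, max_fail_rate = max_fail_rate
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("mtram_study", class(out))
  out
}

run_scenario <- function(gamma1, estimator, n_reps, n_clusters,
                         cluster_size, beta, baseline_df, order, B_ci,
                         level, seed, max_fail_rate) {
  Q <- length(beta)
  true_mu <- beta / sqrt(1 + gamma1^2)
  covs <- paste0("x", seq_len(Q))
  est <- matrix(NA_real_, n_reps, Q)
  low <- matrix(NA_real_, n_reps, Q)
  hig <- matrix(NA_real_, n_reps, Q)
  failed <- logical(n_reps)
  a <- (1 - level) / 2
  for (r in seq_len(n_reps)) {
    rep_res <- tryCatch(
      {
        d <- simulate_clustered(
          n_clusters = n_clusters, cluster_size = cluster_size,
          gamma1 = gamma1, beta = beta, baseline_df = baseline_df,
          seed = seed + r
        )
        if (estimator == "binary") {
          d <- dichotomize_median(d)
          fit <- fit_mtram(d,
            response = "y_bin", cluster = "cluster",
            covariates = covs, link = "logit", basis = "binary"
          )
        } else {
          fit <- fit_mtram(d,
            response = "y", cluster = "cluster",
            covariates = covs, link = "logit", basis = "bernstein",
            order = order
          )
        }
        Ptot <- fit$spec$P * fit$spec$S
        idx <- Ptot + seq_len(Q + 1L) # (beta, gamma1)
        V <- fit$vcov[idx, idx]
        draws <- draw_mvn(B_ci, c(fit$beta, fit$gamma), V)
        g <- pmax(draws[, Q + 1L], 0)
        mu_draws <- draws[, seq_len(Q), drop = FALSE] / sqrt(1 + g^2)
        list(
          mu = fit$beta / sqrt(1 + fit$gamma[1L]^2),
          lo = apply(mu_draws, 2L, stats::quantile, probs = a),
          hi = apply(mu_draws, 2L, stats::quantile, probs = 1 - a)
        )
      },
      error = function(e) NULL
    )
    if (is.null(rep_res)) {
      failed[r] <- TRUE
    } else {
      est[r, ] <- rep_res$mu
      low[r, ] <- rep_res$lo
      hig[r, ] <- rep_res$hi
    }
  }
  n_failed <- sum(failed)
  if (n_failed > max_fail_rate * n_reps) {
    stop(
      "scenario gamma1 = ", gamma1, " (", estimator, "): ", n_failed,
      " of ", n_reps, " replicates failed.",
      call. = FALSE
    )
  }
  ok <- !failed
  n_ok <- sum(ok)
  sq_err <- (est[ok, , drop = FALSE] - rep(true_mu, each = n_ok))^2
  width <- hig[ok, , drop = FALSE] - low[ok, , drop = FALSE]
  cover <- low[ok, , drop = FALSE] <= rep(true_mu, each = n_ok) &
    rep(true_mu, each = n_ok) <= hig[ok, , drop = FALSE]
  cov_hat <- colMeans(cover)
  tibble::tibble(
    estimator = estimator, gamma1 = gamma1,
    effect = paste0("mu", seq_len(Q)),
    true_mu = true_mu,
    mse = colMeans(sq_err),
    mse_se = apply(sq_err, 2L, sd) / sqrt(n_ok),
    ci_width = colMeans(width),
    ci_width_se = apply(width, 2L, sd) / sqrt(n_ok),
    coverage = cov_hat,
    coverage_se = sqrt(cov_hat * (1 - cov_hat) / n_ok),
    n_reps = n_ok, n_failed = n_failed
  )
}
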