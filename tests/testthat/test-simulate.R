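test_that("the generator is reproducible and has the documented shape", {
  d1 <- simulate_clustered(n_clusters = 20, cluster_size = 5, seed = 4)
  d2 <- simulate_clustered(n_clusters = 20, cluster_size = 5, seed = 4)
  expect_equal(d1, d2)
  expect_equal(nrow(d1), 100L)
  expect_equal(names(d1), c("cluster", "obs", "x1", "x2", "x3", "y"))
  expect_equal(unname(table(d1$cluster)), rep(5L, 20L), ignore_attr = TRUE)
  expect_true(all(d1$y > 0))
  expect_true(all(d1[c("x1", "x2", "x3")] >= 0 & d1[c("x1", "x2", "x3")] <= 1))
})

test_that("baseline margins are chi-squared at beta = 0", {
  d <- simulate_clustered(
    n_clusters = 4000, cluster_size = 5, gamma1 = 1,
    beta = c(0, 0, 0), seed = 8
  )
  ks <- suppressWarnings(stats::ks.test(d$y, stats::pchisq, df = 9))
  expect_gt(ks$p.value, 0.01)
})

test_that("within-cluster dependence increases with gamma1", {
  rho_of <- function(g) {
    d <- simulate_clustered(
      n_clusters = 1500, cluster_size = 2, gamma1 = g,
      beta = c(0, 0, 0), seed = 12
    )
    w <- matrix(d$y, ncol = 2, byrow = TRUE)
    stats::cor(w[, 1], w[, 2], method = "spearman")
  }
  r <- vapply(c(0, 1, 3), rho_of, 0)
  expect_lt(abs(r[1]), 0.06)
  expect_gt(r[2], r[1] + 0.1)
  expect_gt(r[3], r[2] + 0.1)
})

test_that("median dichotomization splits the pooled sample in half", {
  d <- simulate_clustered(n_clusters = 50, seed = 3)
  db <- dichotomize_median(d)
  expect_true(all(db$y_bin %in% c(0, 1)))
  expect_equal(mean(db$y_bin), 0.5, tolerance = 0.01)
  expect_equal(db$y_bin, as.numeric(d$y > median(d$y)))
})

test_that("bivariate density marginalizes to the chi-squared baseline", {
  y1 <- seq(0.5, 30, by = 0.5)
  y2 <- seq(1e-3, 80, length.out = 2001)
  dens <- bivariate_density(1, y1, y2)
  wide <- matrix(dens$density, nrow = length(y1))
  marg <- apply(wide, 1, function(f) {
    sum((f[-1] + f[-length(f)]) / 2 * diff(y2))
  })
  expect_lt(max(abs(marg - dchisq(y1, 9))), 1e-3)
})

test_that("independence copula factorizes the bivariate density", {
  y <- c(2, 5, 9, 14)
  dens <- bivariate_density(0, y, y)
  expect_equal(
    dens$density,
    as.numeric(outer(dchisq(y, 9), dchisq(y, 9)))[seq_len(nrow(dens))],
    tolerance = 1e-12
  )
})
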