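test_that("Bernstein rows form a partition of unity and hit the endpoints", {
  sp <- basis_spec("bernstein", order = 6, support = c(1, 20))
  y <- seq(1, 20, length.out = 101)
  A <- basis_row(sp, y)
  expect_equal(rowSums(A), rep(1, length(y)), tolerance = 1e-12)
  expect_equal(A[1, ], c(1, numeric(6)), tolerance = 1e-12)
  expect_equal(A[nrow(A), ], c(numeric(6), 1), tolerance = 1e-12)
})

test_that("increasing coefficients give an increasing transformation", {
  sp <- basis_spec("bernstein", order = 5, support = c(0, 1))
  theta <- cumsum(c(-2, rexp(5)))
  y <- seq(0, 1, length.out = 200)
  h <- drop(basis_row(sp, y) %*% theta)
  expect_true(all(diff(h) > 0))
  hp <- drop(basis_deriv_row(sp, y) %*% theta)
  expect_true(all(hp > 0))
})

test_that("basis_deriv_row matches finite differences", {
  for (kind in c("bernstein", "linear", "loglinear")) {
    sp <- basis_spec(kind, order = 4, support = c(0.5, 8))
    y <- seq(1, 7, length.out = 25)
    h <- 1e-5
    num <- (basis_row(sp, y + h) - basis_row(sp, y - h)) / (2 * h)
    expect_equal(basis_deriv_row(sp, y), num,
      tolerance = 1e-6, info = kind, ignore_attr = TRUE
    )
  }
})

test_that("evaluation outside the support clamps with a condition", {
  sp <- basis_spec("bernstein", order = 3, support = c(0, 1))
  expect_condition(A <- basis_row(sp, c(-0.5, 0.5, 1.7)),
    class = "martram_clamp"
  )
  expect_equal(A[1, ], suppressMessages(basis_row(sp, 0))[1, ])
  expect_equal(A[3, ], suppressMessages(basis_row(sp, 1))[1, ])
})

test_that("discrete bases have the right shape and refuse derivatives", {
  b <- basis_spec("binary_intercept")
  expect_equal(basis_row(b, c(0.5, 0.5)), matrix(1, 2, 1))
  expect_error(basis_deriv_row(b, 0.5))
  o <- basis_spec("ordinal_steps", n_levels = 4)
  A <- basis_row(o, 1:3)
  expect_equal(A, diag(3))
  expect_error(basis_row(o, 4))
  expect_error(basis_deriv_row(o, 1))
})

test_that("monotonicity constraints match the basis kind", {
  expect_equal(
    nrow(monotonicity_constraints(basis_spec("bernstein",
      order = 4, support = c(0, 1)
    ))), 4L
  )
  expect_equal(
    nrow(monotonicity_constraints(basis_spec("linear",
      support = c(0, 1)
    ))), 1L
  )
  expect_equal(
    nrow(monotonicity_constraints(basis_spec("binary_intercept"))), 0L
  )
})
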