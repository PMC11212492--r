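# internal numerical helpers

# log(1 - exp(x)) for x <= 0, stable near both ends
log1mexp <- function(x) {
  stopifnot(all(x <= 0 | is.na(x)))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# log(exp(a) - exp(b)) for a >= b
logspace_sub <- function(a, b) {
  a + log1mexp(pmin(b - a, 0))
}

# row-wise log-sum-exp of a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0 # all -Inf rows -> log(0)
  lse <- mx + log(rowSums(exp(m - mx)))
  lse[apply(m, 1L, function(r) all(r == -Inf))] <- -Inf
  lse
}

# Gauss-Hermite rule transformed to integrate against the standard
# normal density: int phi(s) g(s) ds ~ sum w_k g(s_k)
gauss_hermite_normal <- function(n) {
  gq <- statmod::gauss.quad(n, kind = "hermite")
  list(nodes = sqrt(2) * gq$nodes, weights = gq$weights / sqrt(pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
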