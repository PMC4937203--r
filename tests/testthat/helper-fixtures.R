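# Shared fixtures: small simulated datasets and literal-enumeration oracles
# kept independent of the package's efficient code paths.

make_gaussian_ds <- function(r = 5, cc = 3, N = 6, seed = 1, M = 0,
                             SigmaR = NULL, SigmaC = NULL,
                             family = "gaussian", shape = 1) {
  if (is.null(SigmaR)) SigmaR <- diag(r)
  if (is.null(SigmaC)) SigmaC <- diag(cc)
  cfg <- simulation_config(M = M, SigmaR = SigmaR, SigmaC = SigmaC, N = N,
                           family = family, shape = shape, seed = seed)
  sample_dataset(cfg)
}

# mean-test variance term by literal loops over all distinct quadruples
theta_hat_enumeration <- function(values, P) {
  d <- dim(values); N <- d[3]; r <- d[1]; cc <- d[2]
  tot <- 0; n <- 0
  for (i in 1:N) for (j in 1:N) {
    if (j == i) next
    for (k in 1:N) {
      if (k == i || k == j) next
      for (l in 1:N) {
        if (l == i || l == j || l == k) next
        Dij <- matrix(values[, , i] - values[, , j], r, cc) / sqrt(2)
        Dkl <- matrix(values[, , k] - values[, , l], r, cc) / sqrt(2)
        tot <- tot + sum(diag(Dij %*% P %*% t(Dkl)))^2
        n <- n + 1
      }
    }
  }
  tot / n
}

expect_rel_equal <- function(x, y, tol = 1e-10) {
  expect_lt(abs(x - y) / max(1e-12, abs(y)), tol)
}
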