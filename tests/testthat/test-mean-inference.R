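test_that("mean estimate is the subject average with labels", {
  ds <- make_gaussian_ds(r = 4, cc = 3, N = 5, seed = 13, M = 2)
  mm <- estimate_mean(ds)
  expect_equal(mm$matrix, apply(ds$values, c(1, 2), mean), ignore_attr = TRUE)
  expect_equal(rownames(mm$matrix), ds$row_ids)

  # X1 = A, X2 = -A averages to zero
  A <- matrix(rnorm(6), 3, 2)
  ds2 <- transposable_dataset(array(c(A, -A), c(3, 2, 2)))
  expect_equal(max(abs(estimate_mean(ds2)$matrix)), 0)
})

test_that("group projection is the idempotent centering with the right rank", {
  P <- make_projection(list(c("a", "b")))
  expect_equal(unname(P), matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  # groups of sizes 3, 2, 1 over six columns: rank 3, P^2 = P
  P2 <- make_projection(list(c("a", "b", "c"), c("d", "e"), "f"))
  expect_equal(P2 %*% P2, P2)
  expect_equal(sum(diag(P2)), 3)
  expect_equal(qr(P2)$rank, 3L)

  # all singletons give the zero matrix
  expect_equal(max(abs(make_projection(list("a", "b")))), 0)
  expect_error(make_projection(list(character(0))), "empty group")
  expect_error(make_projection(list(c("a", "b"), c("b", "c"))), "disjoint")
})

test_that("mean-test variance term equals the quadruple enumeration", {
  set.seed(19)
  for (k in 1:3) {
    N <- sample(4:6, 1); r <- sample(3:7, 1); cc <- sample(2:4, 1)
    v <- array(rnorm(r * cc * N, mean = 0.5), c(r, cc, N))
    P <- make_projection(list(paste0("t", seq_len(cc))))
    expect_rel_equal(kronstat:::.theta_hat(v, P),
                     theta_hat_enumeration(v, P))
  }
})

test_that("the conservation statistic is unbiased for tr(M P M')", {
  r <- 30; cc <- 4; N <- 8; reps <- 250
  M <- matrix(0, r, cc); M[1:6, 2] <- 1.5
  P <- make_projection(list(paste0("t", 1:cc)))
  target <- sum((M %*% P) * M)
  ts <- sapply(seq_len(reps), function(b) {
    ds <- make_gaussian_ds(r, cc, N, seed = 90000 + b * N, M = M)
    mean_conservation_test(ds, list(ds$col_ids))$statistic
  })
  expect_lt(abs(mean(ts) - target) / (sd(ts) / sqrt(reps)), 4)
})

test_that("mean test interface: errors, one-sided p, group-shift invariance", {
  ds <- make_gaussian_ds(r = 30, cc = 4, N = 6, seed = 55)
  expect_error(mean_conservation_test(ds, list("t1", "t2")), "vacuous")
  expect_error(mean_conservation_test(make_gaussian_ds(N = 3),
                                      list(c("t1", "t2"))), "N >= 4")
  tst <- mean_conservation_test(ds, list(c("t1", "t2"), c("t3", "t4")))
  expect_equal(tst$p.value, pnorm(tst$z, lower.tail = FALSE))

  # adding a row effect constant within groups leaves the statistic unchanged
  shift <- matrix(rnorm(30), 30, 1)[, rep(1, 4)]
  ds2 <- transposable_dataset(ds$values + as.vector(shift),
                              row_ids = ds$row_ids, col_ids = ds$col_ids)
  tst2 <- mean_conservation_test(ds2, list(c("t1", "t2"), c("t3", "t4")))
  expect_equal(tst2$statistic, tst$statistic, tolerance = 1e-9)
})

test_that("pairwise conservation family has the right shape and BH column", {
  ds <- make_gaussian_ds(r = 40, cc = 9, N = 6, seed = 123, M = 1)
  res <- pairwise_conservation_tests(ds, ds$row_ids[1:10], "t1")
  expect_equal(nrow(res), 8L)
  expect_true(all(res$p.adjusted >= res$p.value))
  expect_equal(res$p.adjusted, bh_adjust(res$p.value))
  expect_error(pairwise_conservation_tests(ds, ds$row_ids[1:3], "t1",
                                           other_cols = c("t1", "t2")),
               "must not appear")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.9, 0.001, 0.04, 0.5, 0.013)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= 0))  # monotone in the p-value ranks
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
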