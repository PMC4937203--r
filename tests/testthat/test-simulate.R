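test_that("structured covariance factory produces the stated forms", {
  expect_equal(random_covariance(3, "ar1", rho = 0), diag(3))
  A <- random_covariance(3, "ar1", rho = 0.5)
  expect_equal(A[1, 3], 0.25)
  expect_equal(A[2, 3], 0.5)

  # compound symmetry eigenvalues: 1 + (p-1) rho and (p-1) copies of 1 - rho
  p <- 5; rho <- 0.3
  ev <- eigen(random_covariance(p, "cs", rho = rho), only.values = TRUE)$values
  expect_equal(sort(ev), sort(c(1 + (p - 1) * rho, rep(1 - rho, p - 1))))

  D <- random_covariance(4, "diag_unequal", lo = 0.5, hi = 1.5)
  expect_equal(diag(D), seq(0.5, 1.5, length.out = 4))
  expect_error(random_covariance(3, "ar1", rho = 1), "\\|rho\\| < 1")
  expect_error(random_covariance(3, "cs", rho = -0.9), "cs requires")
  expect_error(random_covariance(3, "diag_unequal", lo = 0), "0 < lo")
})

test_that("config validates SPD inputs and normalizes the column trace", {
  SR <- random_covariance(4, "ar1", rho = 0.5)
  SC <- 3 * random_covariance(2, "cs", rho = 0.4)  # trace 6, not 2
  cfg <- simulation_config(M = 1, SigmaR = SR, SigmaC = SC, N = 5, seed = 2)
  expect_equal(sum(diag(cfg$SigmaC)), 2)
  # the Kronecker product is unchanged by the renormalization
  expect_equal(kronecker(cfg$SigmaC, cfg$SigmaR), kronecker(SC, SR))

  bad <- SR; bad[1, 2] <- 5
  expect_error(simulation_config(0, bad, diag(2), 4), "symmetric|positive")
  expect_error(simulation_config(0, SR, matrix(0, 2, 2), 4),
               "positive definite")
  expect_error(simulation_config(0, SR, diag(2), 0), "N must be")
})

test_that("generation is deterministic in the seed and extends by subject", {
  SR <- random_covariance(5, "ar1", rho = 0.5)
  SC <- random_covariance(3, "cs", rho = 0.2)
  cfg <- simulation_config(M = 2, SigmaR = SR, SigmaC = SC, N = 4, seed = 42)
  d1 <- sample_dataset(cfg)
  d2 <- sample_dataset(cfg)
  expect_identical(d1$values, d2$values)
  d3 <- sample_dataset(simulation_config(M = 2, SigmaR = SR, SigmaC = SC,
                                         N = 4, seed = 43))
  expect_false(isTRUE(all.equal(d1$values, d3$values)))
  # subject substreams: growing N preserves the first subjects
  d6 <- sample_dataset(simulation_config(M = 2, SigmaR = SR, SigmaC = SC,
                                         N = 6, seed = 42))
  expect_identical(d6$values[, , 1:4], d1$values)
})

test_that("sampled moments match the Kronecker covariance", {
  SR <- random_covariance(3, "ar1", rho = 0.6)
  SC <- random_covariance(2, "cs", rho = 0.4)
  cfg <- simulation_config(M = 1, SigmaR = SR, SigmaC = SC, N = 4000,
                           seed = 99)
  ds <- sample_dataset(cfg)
  X <- t(matrix(ds$values, 6, 4000))           # vectorized subjects
  emp <- cov(X)
  tru <- kronecker(cfg$SigmaC, cfg$SigmaR)
  se <- sqrt((tru^2 + tcrossprod(diag(tru))) / 4000)  # Gaussian cov-of-cov
  expect_true(all(abs(emp - tru) < 4 * se))
  expect_true(all(abs(colMeans(X) - 1) < 4 * sqrt(diag(tru) / 4000)))
})

test_that("scaled-gamma noise is standardized with skewness 2/sqrt(shape)", {
  cfg <- simulation_config(M = 0, SigmaR = diag(1), SigmaC = diag(1),
                           N = 40000, family = "scaled_gamma", shape = 1,
                           seed = 7)
  z <- as.vector(sample_dataset(cfg)$values)
  n <- length(z)
  expect_lt(abs(mean(z)), 4 / sqrt(n))
  expect_lt(abs(var(z) - 1), 4 * sqrt(8 / n))  # Var of gamma variance est.
  sk <- mean(z^3)
  expect_lt(abs(sk - 2), 4 * sqrt(var(z^3) / n))
})

test_that("calibration harness is deterministic and validates scenarios", {
  sc <- list(name = "null-mean", test = "mean_conservation", reps = 20,
             r = 12, c = 3, N = 6)
  a <- calibration_run(sc, seed = 5)
  b <- calibration_run(sc, seed = 5)
  expect_identical(a, b)
  expect_equal(a$reps, 20L)
  expect_true(a$rejection_rate >= 0 && a$rejection_rate <= 1)
  expect_error(calibration_run(list(test = "nope", reps = 5, r = 4, c = 2,
                                    N = 5)), "unknown test")
  expect_error(calibration_run(list(test = "sphericity", reps = 0, r = 4,
                                    c = 2, N = 5)), "reps >= 1")
  expect_error(calibration_run(list(test = "sphericity", reps = 5, r = 4,
                                    N = 5)), "missing field 'c'")

  f <- tempfile()
  calibration_run(sc, seed = 5, out_prefix = f)
  expect_true(file.exists(paste0(f, ".tsv")))
})
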