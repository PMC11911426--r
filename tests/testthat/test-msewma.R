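test_that("in-control transform whitens up to scale", {
  # exact diagonal case: Sigma0 = diag(4, 1) gives A0 = diag(sqrt(5/8), sqrt(5/2))
  h <- history_with_cov(40, c(4, 1), seed = 61)
  expect_equal(cov(h), diag(c(4, 1)), tolerance = 1e-12)
  ic <- estimate_ic_transform(h)
  expect_equal(diag(ic$A0), c(sqrt(5 / 8), sqrt(5 / 2)), tolerance = 1e-8)
  expect_equal(ic$A0[1, 2], 0, tolerance = 1e-8)
  # invariants on random histories
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(3:7, 1)
    h <- matrix(rnorm(60 * p), 60, p) %*% matrix(rnorm(p * p, sd = 0.4) +
                                                   diag(p), p, p)
    ic <- estimate_ic_transform(h)
    S0 <- cov(h)
    expect_equal(crossprod(ic$A0),
                 sum(diag(S0)) / p * solve(S0), tolerance = 1e-8)
    expect_equal(ic$A0 %*% S0 %*% t(ic$A0),
                 sum(diag(S0)) / p * diag(p), tolerance = 1e-8)
  }
  # singular history: duplicated column
  bad <- cbind(rnorm(30), rnorm(30))
  bad <- cbind(bad, bad[, 1])
  expect_error(estimate_ic_transform(bad), "singular covariance: rank 2")
  expect_error(estimate_ic_transform(matrix(rnorm(12), 3, 4)), "m > p")
})

test_that("windowed spatial sign averages unit vectors", {
  ic <- identity_ic(2)
  expect_equal(windowed_spatial_sign(matrix(c(3, 4), 1, 2), ic), c(0.6, 0.8))
  # symmetric rows cancel
  expect_equal(windowed_spatial_sign(rbind(c(2, 1), c(-2, -1)), ic), c(0, 0))
  v <- windowed_spatial_sign(rbind(c(3, 4), c(0, 5)), ic)
  expect_equal(v, c(0.3, 0.9))
  expect_equal(sqrt(sum(v^2)), 0.9487, tolerance = 1e-4)
  # ||v|| <= 1 always
  for (seed in 1:20) {
    set.seed(seed)
    D <- sample(1:12, 1); p <- sample(2:6, 1)
    vv <- windowed_spatial_sign(matrix(rnorm(D * p), D, p), identity_ic(p))
    expect_lte(sqrt(sum(vv^2)), 1 + 1e-12)
  }
  # zero-norm row contributes a zero sign with a warning
  expect_warning(
    vz <- windowed_spatial_sign(rbind(c(0, 0), c(3, 4)), ic), "zero")
  expect_equal(vz, c(0.3, 0.4))
})

test_that("empirical mean spatial sign of spherical data is near zero", {
  set.seed(99)
  v <- windowed_spatial_sign(matrix(rnorm(10000 * 6), ncol = 6),
                             identity_ic(6))
  # each coordinate has variance 1/p; the norm of the mean of 10,000 draws
  # should be a few multiples of sqrt(1/N)
  expect_lt(sqrt(sum(v^2)), 3 / sqrt(10000) * sqrt(1) * 2)
})

test_that("the monitoring statistic follows the quadratic EWMA form", {
  ic <- identity_ic(6)
  # one window of one row with unit sign: S = ((2-l)/l) * p * l^2
  x <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6)
  tr <- run_msewma(x, ic, lambda = 0.2, D = 1, limit = Inf)
  expect_equal(tr$stat[1], (2 - 0.2) / 0.2 * 6 * 0.2^2)
  expect_equal(tr$stat[1], 2.16)
  # recursion against a manual loop
  set.seed(71)
  y <- matrix(rnorm(30 * 4), 30, 4)
  ic4 <- identity_ic(4)
  D <- 5; lam <- 0.3
  tr <- run_msewma(y, ic4, lambda = lam, D = D, limit = Inf)
  w <- rep(0, 4)
  manual <- numeric(30 - D + 1)
  for (k in seq_along(manual)) {
    v <- windowed_spatial_sign(y[k:(k + D - 1), ], ic4)
    w <- (1 - lam) * w + lam * v
    manual[k] <- (2 - lam) / lam * 4 * sum(w^2)
  }
  expect_equal(tr$stat, manual, tolerance = 1e-10)
  expect_true(all(tr$stat >= 0))
})

test_that("the statistic is scale equivariant and root-choice invariant", {
  set.seed(72)
  p <- 5
  h <- matrix(rnorm(100 * p), 100, p)
  ic <- estimate_ic_transform(h)
  x <- matrix(rnorm(40 * p), 40, p)
  tr1 <- run_msewma(x, ic, lambda = 0.2, D = 8, limit = Inf)
  # rescaling the stream about theta0 leaves everything unchanged
  xs <- sweep(3.7 * sweep(x, 2, ic$theta0), 2, ic$theta0, `+`)
  tr2 <- run_msewma(xs, ic, lambda = 0.2, D = 8, limit = Inf)
  expect_equal(tr2$stat, tr1$stat, tolerance = 1e-12)
  # replacing A0 by Q A0 (orthogonal Q) gives the same S
  set.seed(73)
  Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  ic_rot <- ic
  ic_rot$A0 <- Q %*% ic$A0
  tr3 <- run_msewma(x, ic_rot, lambda = 0.2, D = 8, limit = Inf)
  expect_equal(tr3$stat, tr1$stat, tolerance = 1e-10)
})

test_that("alignment and errors match the sliding-window convention", {
  ic <- identity_ic(3)
  x <- matrix(rnorm(12 * 3), 12, 3)
  tr <- run_msewma(x, ic, lambda = 0.2, D = 4, limit = Inf)
  expect_length(tr$stat, 9)
  expect_error(run_msewma(x[1:2, ], ic, lambda = 0.2, D = 4), "too short")
  expect_error(run_msewma(matrix(rnorm(10 * 2), 10, 2), ic, lambda = 0.2,
                          D = 4), "must match")
  expect_error(run_msewma(x, ic, lambda = 1.2, D = 4), "strictly between")
})
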