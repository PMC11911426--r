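test_that("default parameter choices follow the recommended formulas", {
  pp <- default_el_params(10, 46)
  expect_equal(pp$l_n, 10^(5 / 4) * log(10), tolerance = 1e-12)
  expect_equal(pp$l_n, 40.9447, tolerance = 1e-4)
  expect_equal(pp$k_n, sqrt(46 / log(46)), tolerance = 1e-12)
  expect_equal(pp$k_n, 3.4662, tolerance = 1e-4)
  expect_equal(default_el_params(10, 4)$gamma, rep(0.5, 4))
  p22 <- default_el_params(2, 2)
  expect_equal(p22$l_n, 2^(5 / 4) * log(2))
  expect_equal(p22$k_n, 1.69864, tolerance = 1e-5)
  expect_equal(sum(default_el_params(7, 13)$gamma^2), 1, tolerance = 1e-12)
  expect_error(default_el_params(1, 10), "integer >= 2")
  expect_error(default_el_params(10, 1), "integer >= 2")
  expect_error(el_params(10, 4, gamma = rep(1, 4)), "unit")
})

test_that("anchor scale maps deviation to a_n and xi_n", {
  prm <- el_params(10, 4, l_n = 40.9447, k_n = 1.69864, gamma = rep(0.5, 4))
  res <- anchor_scale(rep(0.1, 4), rep(0, 4), prm)
  expect_equal(res$a_n, 40.9447 / sqrt(0.04 + 1.69864 * 0.04),
               tolerance = 1e-10)
  expect_equal(res$a_n, 124.622, tolerance = 1e-4)
  expect_equal(res$xi_n, 12 / (1 + res$a_n), tolerance = 1e-12)
  expect_equal(res$xi_n, 0.09552, tolerance = 1e-4)
  # zero deviation: infinite anchor, xi = 0
  z <- anchor_scale(rep(1, 4), rep(1, 4), prm)
  expect_identical(z$a_n, Inf)
  expect_identical(z$xi_n, 0)
  expect_error(anchor_scale(rep(0, 3), rep(0, 4), prm), "length p")
})

test_that("virtual points conserve the augmented mean", {
  # direct substitution example
  vp <- virtual_points(c(1, 0), c(0, 0), a_n = 3)
  expect_equal(vp$x_n1, c(-3, 0))
  expect_equal(vp$x_n2, c(5, 0))
  # a_n = 0 collapses the first point onto mu0
  vp0 <- virtual_points(c(1, 2), c(0, 1), a_n = 0)
  expect_equal(vp0$x_n1, c(0, 1))
  expect_equal(vp0$x_n2, c(2, 3))
  # zero deviation: both virtual points at mu0
  vpz <- virtual_points(c(2, 2), c(2, 2), a_n = 7)
  expect_equal(vpz$x_n1, c(2, 2))
  expect_equal(vpz$x_n2, c(2, 2))
  expect_error(virtual_points(c(1, 0), c(0, 0), Inf), "finite")
  # property: augmented (n+2)-point mean equals the window mean
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1); p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    mu0 <- rnorm(p)
    a_n <- runif(1, 0, 50)
    vp <- virtual_points(colMeans(x), mu0, a_n)
    aug <- rbind(x, vp$x_n1, vp$x_n2)
    expect_equal(colMeans(aug), colMeans(x), tolerance = 1e-10)
    # equivalently: deviations from mu0 sum to (n+2)(xbar - mu0)
    expect_equal(colSums(sweep(aug, 2, mu0)),
                 (n + 2) * (colMeans(x) - mu0), tolerance = 1e-8)
  }
})

test_that("closed-form log-ratio has the required shape", {
  for (n in c(6, 8, 10)) {
    expect_identical(el_logratio_closed(n, 0), 0)
    grid <- seq(0, n + 2 - 1e-3, length.out = 400)
    W <- el_logratio_closed(n, grid)
    expect_true(all(W >= 0))
    expect_true(all(W[-1] > 0))
    expect_true(all(diff(W) > 0))           # strictly increasing
    # divergence at the right boundary
    expect_gt(el_logratio_closed(n, n + 2 - 1e-9), 30)
  }
  expect_error(el_logratio_closed(10, 12), "\\[0, n \\+ 2\\)")
  expect_error(el_logratio_closed(10, -0.1), "\\[0, n \\+ 2\\)")
})

test_that("small-xi quadratic law bounds the log-ratio", {
  # grid starts where xi^4 clears double-precision evaluation noise
  xi <- seq(0.01, 0.2, length.out = 50)
  for (n in c(6, 8, 10, 20)) {
    W <- el_logratio_closed(n, xi)
    expect_true(all(abs(W - xi^2 / 2) <= xi^4))
  }
})

test_that("trace estimates match direct matrix algebra", {
  # frozen worked example, plug-in mode
  w <- window_sample(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  prm <- el_params(3, 2, k_n = 1.69864, gamma = rep(1 / sqrt(2), 2))
  expect_equal(w$cov, matrix(c(1 / 3, -1 / 6, -1 / 6, 1 / 3), 2, 2))
  tr <- trace_omega_estimates(w, prm, "plug_in")
  expect_equal(tr$tr_omega, 0.94977, tolerance = 1e-4)
  expect_equal(tr$tr_omega_sq, 0.45230, tolerance = 1e-4)
  # independent route: build Omega-hat = S^{1/2} (I + k gg') S^{1/2} explicitly
  for (seed in 1:5) {
    w <- rand_window(12, 4, seed)
    prm <- default_el_params(12, 4)
    e <- eigen(w$cov, symmetric = TRUE)
    S_half <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    Om <- S_half %*% (diag(4) + prm$k_n * tcrossprod(prm$gamma)) %*% S_half
    tr <- trace_omega_estimates(w, prm, "plug_in")
    expect_equal(tr$tr_omega, sum(diag(Om)), tolerance = 1e-10)
    expect_equal(tr$tr_omega_sq, sum(Om * Om), tolerance = 1e-10)
    # bias-corrected mode differs from plug-in exactly by the tr(Sigma^2) term
    trb <- trace_omega_estimates(w, prm, "bias_corrected")
    n <- 12
    S <- w$cov
    corr <- ((n - 1)^2 / ((n - 2) * (n + 1))) *
      (sum(S * S) - sum(diag(S))^2 / (n - 1))
    expect_equal(trb$tr_omega, tr$tr_omega)
    expect_equal(trb$tr_omega_sq - tr$tr_omega_sq, corr - sum(S * S),
                 tolerance = 1e-10)
  }
  # degenerate window
  wd <- window_sample(matrix(1, 5, 3))
  expect_error(trace_omega_estimates(wd, default_el_params(5, 3)),
               "degenerate")
  expect_error(trace_omega_estimates(rand_window(3, 2, 1),
                                     default_el_params(3, 2),
                                     "bias_corrected"),
               "n >= 4")
})

test_that("q_statistic composes its parts and respects invariances", {
  # frozen example: mu0 at the window mean, W = 0 branch
  w <- window_sample(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  prm <- el_params(3, 2, k_n = 1.69864, gamma = rep(1 / sqrt(2), 2))
  qs <- q_statistic(w, c(1 / 3, 1 / 3), prm, "plug_in")
  expect_equal(qs$Q, -0.9986, tolerance = 1e-4)
  expect_identical(qs$W, 0)
  # mu0 = xbar always gives negative Q
  for (seed in 1:5) {
    w <- rand_window(10, 7, seed)
    prm <- default_el_params(10, 7)
    expect_lt(q_statistic(w, w$mean, prm)$Q, 0)
  }
  # permutation invariance of window rows
  w <- rand_window(10, 5, 42)
  prm <- default_el_params(10, 5)
  mu0 <- rep(0.1, 5)
  q1 <- q_statistic(w, mu0, prm)$Q
  set.seed(7)
  for (i in 1:5) {
    wp <- window_sample(w$data[sample(10), ])
    expect_equal(q_statistic(wp, mu0, prm)$Q, q1, tolerance = 1e-12)
  }
  # monotone in the distance of mu0 from the window mean (fixed direction)
  dir <- rep(1 / sqrt(5), 5)
  qs <- vapply(seq(0, 2, by = 0.1), function(t)
    q_statistic(w, w$mean - t * dir, prm)$Q, numeric(1))
  expect_true(all(diff(qs) >= 0))
  expect_error(q_statistic(w, rep(0, 4), prm), "dimension")
})

test_that("large-l_n limit recovers the location-test numerator", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10; p <- 8
    w <- rand_window(n, p, seed)
    prm <- el_params(n, p, l_n = 1e6, k_n = sqrt(p / log(p)))
    mu0 <- rnorm(p, sd = 0.5)
    qs <- q_statistic(w, mu0, prm)
    d <- w$mean - mu0
    target <- n * (sum(d^2) + prm$k_n * sum(prm$gamma * d)^2)
    lhs <- 2 * n * prm$l_n^2 / (n + 2)^2 * qs$W
    expect_lt(abs(lhs - target) / target, 1e-3)
  }
})

test_that("null behaviour of Q over many in-control windows is sane", {
  set.seed(202)
  x <- matrix(rnorm(100008 * 46), ncol = 46)
  q <- q_seq(x, 10, rep(0, 46))
  q10 <- q[seq(1, length(q), by = 10)]   # disjoint windows
  expect_gte(length(q10), 10000)
  expect_true(is.finite(mean(q10)))
  expect_gt(var(q10), 0.2)
  expect_lt(var(q10), 5)
})

test_that("reduced numeric solver reproduces the closed-form log-ratio", {
  # zero-deviation limit: uniform weights, ratio 1
  w <- rand_window(10, 4, 3)
  prm <- default_el_params(10, 4)
  red0 <- el_reduced_numeric(w, w$mean, prm)
  expect_equal(red0$p_common, 1 / 12)
  expect_equal(red0$neg2logR, 0)
  # property sweep: weights valid and the optimum matches the closed form
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(c(6, 8, 10), 1); p <- sample(3:8, 1)
    w <- rand_window(n, p, seed + 1000)
    prm <- default_el_params(n, p)
    mu0 <- rnorm(p, sd = 0.4)
    red <- el_reduced_numeric(w, mu0, prm)
    expect_true(red$feasible)
    expect_true(all(c(red$p_common, red$q1, red$q2) >= 0))
    expect_equal(n * red$p_common + red$q1 + red$q2, 1, tolerance = 1e-8)
    W <- q_statistic(w, mu0, prm)$W
    expect_equal(red$neg2logR, W, tolerance = 1e-6)
  }
})

test_that("compiled and pure-R statistic engines agree", {
  set.seed(5)
  x <- matrix(rnorm(80 * 12), 80, 12)
  mu0 <- rnorm(12, sd = 0.2)
  for (mode in c("bias_corrected", "plug_in")) {
    expect_equal(q_seq(x, 10, mu0, mode = mode),
                 q_seq(x, 10, mu0, mode = mode, engine = "r"),
                 tolerance = 1e-10)
  }
  expect_error(q_seq(x[1:5, ], 10, mu0), "shorter")
})
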