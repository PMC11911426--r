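# Shared fixtures built in code.

rand_window <- function(n, p, seed) {
  set.seed(seed)
  window_sample(matrix(rnorm(n * p), n, p))
}

# ic_transform with identity standardization (theta0 = 0, A0 = I).
identity_ic <- function(p) {
  structure(list(theta0 = rep(0, p), A0 = diag(p), Sigma0 = diag(p), p = p),
            class = "ic_transform")
}

# History matrix whose sample covariance is EXACTLY the diagonal matrix
# diag(d): orthonormalize centred Gaussian columns, then rescale.
history_with_cov <- function(m, d, seed) {
  set.seed(seed)
  z <- matrix(rnorm(m * length(d)), m, length(d))
  z <- sweep(z, 2, colMeans(z))
  q <- qr.Q(qr(z))
  sweep(q, 2, sqrt((m - 1) * d), `*`)
}

# Memoryless dummy chart: iid Uniform(0,1) statistics (geometric run lengths).
unif_stat_fn <- function(s, h) {
  set.seed(s)
  runif(h)
}
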