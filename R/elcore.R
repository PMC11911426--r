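## Core of the high-dimensional empirical-likelihood ratio statistic.
##
## A window of n observations in p dimensions (typically n = D << p) is tested
## against a hypothesised mean mu0.  Because the convex hull of n points almost
## never covers mu0 when p/n > 1/2, two artificial "virtual" points are
## appended on the line through the sample mean and mu0; the anchor scale a_n
## controls how far out they sit and makes the empirical-likelihood mean
## constraint feasible without inverting the sample covariance.  The log-ratio
## then has a closed form in the single scalar xi_n, and the standardized
## statistic Q contrasts it with trace estimates of
## Omega = Sigma^{1/2} (I_p + k_n gamma gamma') Sigma^{1/2}.

#' Tuning parameters of the empirical-likelihood statistic
#'
#' Bundles the window size `n`, dimension `p`, the virtual-point scale `l_n`,
#' the direction weight `k_n` and the unit projection direction `gamma`.
#' [default_el_params()] fills in the recommended choices
#' `l_n = n^(5/4) log n`, `k_n = sqrt(p / log p)` and
#' `gamma = (1, ..., 1)' / sqrt(p)` (natural logarithms throughout).
#'
#' @param n window sample size, integer `>= 2`.
#' @param p dimension, integer `>= 2`.
#' @param l_n positive scale of the virtual-point anchor.
#' @param k_n positive weight of the projection direction.
#' @param gamma numeric `p`-vector of unit Euclidean norm.
#' @return An object of class `"el_params"`: a list with elements `n`, `p`,
#'   `l_n`, `k_n`, `gamma`.
#' @examples
#' default_el_params(10, 46)
#' @export
el_params <- function(n, p, l_n = NULL, k_n = NULL, gamma = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  if (length(p) != 1L || !is.finite(p) || p < 2 || p != round(p))
    stop("'p' must be a single integer >= 2")
  n <- as.integer(n); p <- as.integer(p)
  l_n <- l_n %||% (n^(5 / 4) * log(n))
  k_n <- k_n %||% sqrt(p / log(p))
  gamma <- gamma %||% (rep(1, p) / sqrt(p))
  if (!is.numeric(l_n) || length(l_n) != 1L || !is.finite(l_n) || l_n <= 0)
    stop("'l_n' must be a positive scalar")
  if (!is.numeric(k_n) || length(k_n) != 1L || !is.finite(k_n) || k_n <= 0)
    stop("'k_n' must be a positive scalar")
  if (length(gamma) != p) stop("'gamma' must have length p")
  nrm <- sqrt(sum(gamma^2))
  if (abs(nrm - 1) > 1e-8) stop("'gamma' must have unit Euclidean norm")
  gamma <- gamma / nrm
  structure(list(n = n, p = p, l_n = l_n, k_n = k_n, gamma = gamma),
            class = "el_params")
}

#' @rdname el_params
#' @export
default_el_params <- function(n, p) el_params(n, p)

#' @export
print.el_params <- function(x, ...) {
  cat(sprintf("EL parameters: n = %d, p = %d, l_n = %.4f, k_n = %.4f\n",
              x$n, x$p, x$l_n, x$k_n))
  invisible(x)
}

#' Sliding-window sample with summary statistics
#'
#' Wraps an `n x p` data window together with its column mean and sample
#' covariance (divisor `n - 1`).
#'
#' @param data numeric matrix with `n >= 2` rows.
#' @return An object of class `"window_sample"`: list with `data`, `mean`,
#'   `cov`, `n`, `p`.
#' @export
window_sample <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 2 || ncol(data) < 1)
    stop("'data' must be a numeric matrix with at least 2 rows")
  structure(list(data = data, mean = colMeans(data), cov = stats::cov(data),
                 n = nrow(data), p = ncol(data)),
            class = "window_sample")
}

#' Anchor scale and xi of the virtual-point construction
#'
#' Computes `a_n = l_n / sqrt(||xbar - mu0||^2 + k_n (gamma'(xbar - mu0))^2)`
#' and `xi_n = (n + 2) / (1 + a_n)`.  When `xbar == mu0` the anchor is
#' infinite and `xi_n = 0` (the continuous limit; the log-ratio is then 0).
#'
#' @param mean,mu0 numeric `p`-vectors: window mean and hypothesised mean.
#' @param params an [el_params()] object.
#' @return list with elements `a_n` (possibly `Inf`) and `xi_n` in `[0, n+2)`.
#' @export
anchor_scale <- function(mean, mu0, params) {
  stopifnot(inherits(params, "el_params"))
  if (length(mean) != params$p || length(mu0) != params$p)
    stop("'mean' and 'mu0' must have length p")
  d <- as.numeric(mean) - as.numeric(mu0)
  den2 <- sum(d^2) + params$k_n * sum(params$gamma * d)^2
  if (den2 <= 0) return(list(a_n = Inf, xi_n = 0))
  a_n <- params$l_n / sqrt(den2)
  list(a_n = a_n, xi_n = (params$n + 2) / (1 + a_n))
}

#' Virtual points appended to the window
#'
#' `x_{n+1} = mu0 - a_n (xbar - mu0)` and
#' `x_{n+2} = mu0 + (2 + a_n) (xbar - mu0)`.  The augmented `(n+2)`-point set
#' keeps the original mean `xbar`.
#'
#' @inheritParams anchor_scale
#' @param a_n finite nonnegative anchor scale; an infinite anchor must be
#'   short-circuited by the caller (the log-ratio is 0 there).
#' @return list with `x_n1` and `x_n2`, numeric `p`-vectors.
#' @export
virtual_points <- function(mean, mu0, a_n) {
  if (length(a_n) != 1L || !is.finite(a_n) || a_n < 0)
    stop("'a_n' must be a finite nonnegative scalar")
  if (length(mean) != length(mu0)) stop("'mean' and 'mu0' length mismatch")
  d <- as.numeric(mean) - as.numeric(mu0)
  list(x_n1 = mu0 - a_n * d, x_n2 = mu0 + (2 + a_n) * d)
}

#' Closed-form empirical-likelihood log-ratio
#'
#' Evaluates `W = -2 log R(mu0, k_n)` as a function of `xi_n`:
#' \deqn{W = -2\Big(n \log\big[1 + \tfrac1n\{1 - r\}\big]
#'   + \log\{\tfrac12 + \tfrac{\xi}{2} + \tfrac r2\}
#'   + \log\{\tfrac12 - \tfrac{\xi}{2} + \tfrac r2\}\Big),\quad
#'   r = \sqrt{1 + \tfrac{n}{n+2}\xi^2}.}
#' `W(0) = 0`, `W` is nonnegative and increases to `+Inf` as
#' `xi -> (n + 2)^-`; for small `xi`, `W ~ xi^2 / 2`.
#'
#' @param n window sample size.
#' @param xi_n numeric vector of values in `[0, n + 2)`.
#' @return numeric vector of log-ratio values, same length as `xi_n`.
#' @export
el_logratio_closed <- function(n, xi_n) {
  if (any(!is.finite(xi_n)) || any(xi_n < 0) || any(xi_n >= n + 2))
    stop("'xi_n' must lie in [0, n + 2)")
  r <- sqrt(1 + n / (n + 2) * xi_n^2)
  t1 <- pmax(1 + (1 - r) / n, 1e-300)
  t2 <- 0.5 + xi_n / 2 + r / 2
  t3 <- pmax(0.5 - xi_n / 2 + r / 2, 1e-300)
  pmax(-2 * (n * log(t1) + log(t2) + log(t3)), 0)
}

#' Trace estimates of Omega and Omega squared
#'
#' Uses the identities `tr(Omega) = tr(Sigma) + k_n gamma' Sigma gamma` and
#' `tr(Omega^2) = tr(Sigma^2) + 2 k_n gamma' Sigma^2 gamma +
#' k_n^2 (gamma' Sigma gamma)^2`.  `mode = "plug_in"` substitutes the sample
#' covariance S for Sigma everywhere; `mode = "bias_corrected"` (default)
#' replaces `tr(Sigma^2)` by the unbiased
#' `((n-1)^2 / ((n-2)(n+1))) [tr(S^2) - tr(S)^2 / (n-1)]`, which matters when
#' the window size is far below the dimension.
#'
#' @param window a [window_sample()].
#' @param params an [el_params()] object.
#' @param mode `"bias_corrected"` (needs `n >= 4`) or `"plug_in"` (`n >= 2`).
#' @return list with `tr_omega` and `tr_omega_sq` (`> 0`).
#' @export
trace_omega_estimates <- function(window, params,
                                  mode = c("bias_corrected", "plug_in")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "window_sample"), inherits(params, "el_params"))
  if (window$p != params$p) stop("window dimension does not match params")
  n <- window$n
  if (mode == "bias_corrected" && n < 4)
    stop("bias-corrected trace estimates need n >= 4")
  S <- window$cov
  tr_s <- sum(diag(S))
  tr_s2 <- sum(S * S)
  if (tr_s2 <= 0) stop("degenerate window: all rows identical")
  g <- params$gamma
  Sg <- drop(S %*% g)
  gSg <- sum(g * Sg)
  gS2g <- sum(Sg^2)
  tr_sig2 <- if (mode == "bias_corrected") {
    ((n - 1)^2 / ((n - 2) * (n + 1))) * (tr_s2 - tr_s^2 / (n - 1))
  } else tr_s2
  k <- params$k_n
  out <- list(tr_omega = tr_s + k * gSg,
              tr_omega_sq = tr_sig2 + 2 * k * gS2g + k^2 * gSg^2)
  if (out$tr_omega_sq <= 0) stop("degenerate window: nonpositive tr(Omega^2)")
  out
}

#' Standardized empirical-likelihood window statistic Q
#'
#' Composes [anchor_scale()], [el_logratio_closed()] and
#' [trace_omega_estimates()]:
#' \deqn{Q = \{2\,\widehat{tr}(\Omega^2)\}^{-1/2}
#'   \Big\{\tfrac{2 n l_n^2}{(n+2)^2} W(\mu_0, k_n) - \widehat{tr}(\Omega)\Big\}.}
#' When the window mean equals `mu0`, `W = 0` and
#' `Q = -tr(Omega) / sqrt(2 tr(Omega^2)) < 0`.
#'
#' @inheritParams trace_omega_estimates
#' @param mu0 hypothesised mean, numeric `p`-vector.
#' @return An object of class `"el_statistics"`: list with `a_n`, `xi_n`, `W`,
#'   `tr_omega`, `tr_omega_sq`, `Q`.
#' @examples
#' w <- window_sample(matrix(rnorm(10 * 46), 10, 46))
#' q_statistic(w, rep(0, 46), default_el_params(10, 46))
#' @export
q_statistic <- function(window, mu0, params,
                        mode = c("bias_corrected", "plug_in")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "window_sample"), inherits(params, "el_params"))
  if (window$n != params$n) stop("window rows must equal params$n")
  if (window$p != params$p || length(mu0) != params$p)
    stop("dimension mismatch between window, mu0 and params")
  n <- params$n
  an <- anchor_scale(window$mean, mu0, params)
  W <- if (is.finite(an$a_n)) el_logratio_closed(n, an$xi_n) else 0
  tr <- trace_omega_estimates(window, params, mode)
  fac <- 2 * n * params$l_n^2 / (n + 2)^2
  Q <- (fac * W - tr$tr_omega) / sqrt(2 * tr$tr_omega_sq)
  structure(list(a_n = an$a_n, xi_n = an$xi_n, W = W,
                 tr_omega = tr$tr_omega, tr_omega_sq = tr$tr_omega_sq, Q = Q),
            class = "el_statistics")
}

#' @export
print.el_statistics <- function(x, ...) {
  cat(sprintf(paste0("EL window statistic:\n  a_n = %.6g, xi_n = %.6g, ",
                     "W = %.6g\n  tr(Omega) = %.6g, tr(Omega^2) = %.6g\n",
                     "  Q = %.6g\n"),
              x$a_n, x$xi_n, x$W, x$tr_omega, x$tr_omega_sq, x$Q))
  invisible(x)
}

#' Reduced numeric empirical-likelihood solver (diagnostic oracle)
#'
#' Solves the augmented-sample empirical-likelihood program restricted to a
#' common weight on the n original points plus free weights on the two virtual
#' points (the orthogonal deviation components of the originals cancel under
#' equal weights, so the mean constraint is one-dimensional along
#' `xbar - mu0`).  The two linear constraints leave one degree of freedom,
#' optimized numerically.  Intended as an independent cross-check of the
#' closed-form log-ratio, not as the production path.
#'
#' @inheritParams q_statistic
#' @return list with `p_common`, `q1`, `q2`, `neg2logR`, `feasible`.
#' @export
el_reduced_numeric <- function(window, mu0, params) {
  stopifnot(inherits(window, "window_sample"), inherits(params, "el_params"))
  n <- window$n
  an <- anchor_scale(window$mean, mu0, params)
  if (!is.finite(an$a_n)) {
    w <- 1 / (n + 2)
    return(list(p_common = w, q1 = w, q2 = w, neg2logR = 0, feasible = TRUE))
  }
  a <- an$a_n
  ## q1 - q2 = 1/(1+a); q2 = t in (0, tmax); p = (1 - q1 - q2)/n
  dq <- 1 / (1 + a)
  tmax <- (1 - dq) / 2
  if (tmax <= 0)
    return(list(p_common = NA_real_, q1 = NA_real_, q2 = NA_real_,
                neg2logR = NA_real_, feasible = FALSE))
  obj <- function(t) {
    q1 <- t + dq; q2 <- t
    pc <- (1 - q1 - q2) / n
    if (pc <= 0 || q2 <= 0) return(-Inf)
    n * log((n + 2) * pc) + log((n + 2) * q1) + log((n + 2) * q2)
  }
  opt <- stats::optimize(obj, c(1e-14, tmax - 1e-14), maximum = TRUE,
                         tol = 1e-12)
  q2 <- opt$maximum; q1 <- q2 + dq
  list(p_common = (1 - q1 - q2) / n, q1 = q1, q2 = q2,
       neg2logR = -2 * opt$objective, feasible = TRUE)
}

#' Per-window statistic sequence over a stream
#'
#' Computes the standardized empirical-likelihood statistic Q on every sliding
#' window of `D` consecutive rows (windows `k..k+D-1`,
#' `k = 1, ..., T - D + 1`).  The default engine is compiled; `engine = "r"`
#' runs the pure-R path window by window (used for cross-validation and
#' debugging).
#'
#' @param stream numeric `T x p` matrix, rows in time order.
#' @param D window size (`= params$n`).
#' @param mu0 hypothesised in-control mean, length-`p` vector.
#' @param params an [el_params()] object with `n = D`, `p = ncol(stream)`.
#' @param mode trace-estimator mode, see [trace_omega_estimates()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return numeric vector of length `T - D + 1`.
#' @export
q_seq <- function(stream, D, mu0, params = default_el_params(D, ncol(stream)),
                  mode = c("bias_corrected", "plug_in"),
                  engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stream <- as.matrix(stream)
  if (nrow(stream) < D) stop("stream shorter than window size D")
  if (params$n != D) stop("params$n must equal D")
  if (params$p != ncol(stream) || length(mu0) != ncol(stream))
    stop("stream columns must match params$p and length(mu0)")
  if (mode == "bias_corrected" && D < 4)
    stop("bias-corrected trace estimates need D >= 4")
  if (engine == "cpp") {
    q_seq_cpp(stream, as.integer(D), as.numeric(mu0), params$l_n, params$k_n,
              params$gamma, mode == "bias_corrected")
  } else {
    m <- nrow(stream) - D + 1
    vapply(seq_len(m), function(k) {
      q_statistic(window_sample(stream[k:(k + D - 1), , drop = FALSE]),
                  mu0, params, mode)$Q
    }, numeric(1))
  }
}
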