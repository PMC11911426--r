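## MSEWMA comparator: affine spatial-sign standardization, window averaging,
## vector EWMA, quadratic monitoring statistic.

#' Estimate the in-control spatial-sign transform
#'
#' From a Phase-I history of `m > p` in-control rows, sets
#' `theta0 = colMeans(history)` and `A0` to the symmetric square root of
#' `p^{-1} tr(Sigma0) Sigma0^{-1}` with `Sigma0` the sample covariance.  The
#' transform whitens up to scale: `A0 Sigma0 A0' = (tr(Sigma0)/p) I`.  Any
#' root of `A0'A0 = p^{-1} tr(Sigma0) Sigma0^{-1}` yields the same monitoring
#' statistic; the symmetric (spectral) root is the implementation canon.
#'
#' @param history numeric `m x p` matrix of in-control observations, `m > p`.
#' @return An object of class `"ic_transform"`: list with `theta0`, `A0`,
#'   `Sigma0`, `p`.
#' @export
estimate_ic_transform <- function(history) {
  history <- as.matrix(history)
  m <- nrow(history); p <- ncol(history)
  if (m <= p) stop("need more history rows than dimensions (m > p)")
  theta0 <- colMeans(history)
  Sigma0 <- stats::cov(history)
  e <- eigen(Sigma0, symmetric = TRUE)
  tol <- max(e$values) * p * .Machine$double.eps
  rank <- sum(e$values > tol)
  if (rank < p)
    stop("singular covariance: rank ", rank, " < p = ", p)
  scale <- sum(e$values) / p
  A0 <- e$vectors %*% (sqrt(scale / e$values) * t(e$vectors))
  structure(list(theta0 = theta0, A0 = A0, Sigma0 = Sigma0, p = p),
            class = "ic_transform")
}

#' @export
print.ic_transform <- function(x, ...) {
  cat(sprintf("In-control spatial-sign transform: p = %d, tr(Sigma0) = %.4g\n",
              x$p, sum(diag(x$Sigma0))))
  invisible(x)
}

#' Window-averaged spatial sign
#'
#' `v = (1/D) sum_j A0 (x_j - theta0) / ||A0 (x_j - theta0)||` over the `D`
#' rows of the window.  Rows mapping exactly to `theta0` contribute a zero
#' sign vector (with a warning).  Always `||v|| <= 1`.
#'
#' @param window numeric `D x p` matrix.
#' @param ic an [estimate_ic_transform()] object.
#' @return numeric `p`-vector.
#' @export
windowed_spatial_sign <- function(window, ic) {
  stopifnot(inherits(ic, "ic_transform"))
  window <- as.matrix(window)
  if (ncol(window) != ic$p) stop("window columns must match ic$p")
  Y <- sweep(window, 2, ic$theta0) %*% t(ic$A0)
  nrm <- sqrt(rowSums(Y^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " window row(s) equal theta0; their sign is zero")
    nrm[zero] <- 1
    Y[zero, ] <- 0
  }
  colMeans(Y / nrm)
}

## Full MSEWMA statistic sequence over a stream, vectorized: transform and
## row-normalize once, window-average via cumulative sums, then the vector
## EWMA w_t = (1-lambda) w_{t-1} + lambda v_t from w_0 = 0 and
## S_t = ((2-lambda)/lambda) p ||w_t||^2.
msewma_stat_seq <- function(stream, ic, D, lambda) {
  stopifnot(inherits(ic, "ic_transform"))
  stream <- as.matrix(stream)
  T_ <- nrow(stream); p <- ncol(stream)
  if (p != ic$p) stop("stream columns must match ic$p")
  if (T_ < D) stop("stream too short: need at least D = ", D, " rows")
  if (lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly between 0 and 1")
  Y <- sweep(stream, 2, ic$theta0) %*% t(ic$A0)
  nrm <- sqrt(rowSums(Y^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " stream row(s) equal theta0; their sign is zero")
    nrm[zero] <- 1
    Y[zero, ] <- 0
  }
  U <- Y / nrm
  cs <- matrix(apply(U, 2, cumsum), nrow = T_)
  m <- T_ - D + 1
  if (m == 1L) {
    V <- matrix(cs[D, ] / D, 1L, p)
  } else {
    V <- (cs[D:T_, , drop = FALSE] -
            rbind(0, cs[seq_len(m - 1), , drop = FALSE])) / D
  }
  W <- apply(V, 2, function(v)
    stats::filter(lambda * v, 1 - lambda, method = "recursive", init = 0))
  W <- matrix(as.numeric(W), nrow = m)
  list(S = (2 - lambda) / lambda * p * rowSums(W^2),
       v_norm = sqrt(rowSums(V^2)))
}

#' Run the MSEWMA chart over an observation stream
#'
#' Sliding-window alignment is identical to [run_delewma()]: statistic `k`
#' uses stream rows `k .. k + D - 1`.  The vector EWMA `w` is seeded at zero,
#' and `S = ((2 - lambda) / lambda) p w'w` is compared against the upper
#' control limit `L2`.
#'
#' @param stream numeric `T x p` matrix of time-ordered observations.
#' @param ic an [estimate_ic_transform()] object.
#' @param lambda EWMA smoothing weight in (0, 1).
#' @param D sliding-window size (`>= 1`).
#' @param limit upper control limit L2.
#' @param stop_at_first_alarm truncate the trace at the first exceedance.
#' @return An object of class `c("msewma", "spc_chart")`; `stat` holds the
#'   `S` sequence and `q` the per-window spatial-sign norms `||v||`.
#' @examples
#' ic <- estimate_ic_transform(matrix(rnorm(200 * 6), 200, 6))
#' run_msewma(matrix(rnorm(50 * 6), 50, 6), ic, lambda = 0.2, D = 10)
#' @export
run_msewma <- function(stream, ic, lambda, D, limit = Inf,
                       stop_at_first_alarm = FALSE) {
  res <- msewma_stat_seq(stream, ic, D, lambda)
  chart_trace("MSEWMA", res$v_norm, res$S, limit, lambda, D, 0,
              stop_at_first_alarm)
}
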