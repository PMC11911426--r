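## D-ELEWMA: EWMA smoothing of the sliding-window empirical-likelihood
## statistic, with a one-sided upper alarm rule.

#' One EWMA update
#'
#' `new = (1 - lambda) * prev + lambda * q`, the convex combination underlying
#' all EWMA-type charts.
#'
#' @param prev previous smoothed value.
#' @param q new raw statistic.
#' @param lambda smoothing weight in the open interval (0, 1).
#' @return updated smoothed value.
#' @export
ewma_update <- function(prev, q, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly between 0 and 1")
  (1 - lambda) * prev + lambda * q
}

## Recursive EWMA over a whole statistic sequence, seeded at t0.
ewma_smooth <- function(q, lambda, t0) {
  if (length(q) == 0L) return(numeric(0))
  if (lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly between 0 and 1")
  as.numeric(stats::filter(lambda * q, 1 - lambda, method = "recursive",
                           init = t0))
}

## Assemble the common chart-trace object shared by both charts.
chart_trace <- function(chart, q, stat, limit, lambda, D, t0,
                        stop_at_first_alarm) {
  idx <- which(stat > limit)
  first_alarm <- if (length(idx)) idx[1L] else NA_integer_
  if (isTRUE(stop_at_first_alarm) && !is.na(first_alarm)) {
    keep <- seq_len(first_alarm)
    q <- q[keep]; stat <- stat[keep]
  }
  structure(list(chart = chart, t = seq_along(stat), q = q, stat = stat,
                 limit = limit, lambda = lambda, D = D, t0 = t0,
                 first_alarm = first_alarm, alarmed = !is.na(first_alarm)),
            class = c(tolower(gsub("-", "", chart)), "spc_chart"))
}

#' Run the D-ELEWMA chart over an observation stream
#'
#' Emits one statistic per fully formed window: statistic `k` is computed on
#' stream rows `k .. k + D - 1`, so a stream of `T` rows yields `T - D + 1`
#' monitored steps and run lengths are counted in emitted statistics.  The
#' EWMA is seeded at `t0` and an alarm is raised at the first step with
#' `stat > limit` (one-sided upper rule).
#'
#' Because the in-control mean of the window statistic Q is negative, the
#' calibrated upper limit is typically negative as well; seed `t0` at the
#' in-control mean of Q (reported by [calibrate_delewma()] as `ic_stat_mean`)
#' rather than at 0, otherwise the chart starts above its own limit.
#'
#' @param stream numeric `T x p` matrix of time-ordered observations.
#' @param mu0 in-control mean on the monitoring scale, length-`p` vector.
#' @param lambda EWMA smoothing weight in (0, 1).
#' @param D sliding-window size (`>= 2`; `>= 4` for the default
#'   bias-corrected trace mode).
#' @param limit upper control limit L1 (`Inf` disables alarms, `-Inf` alarms
#'   immediately).
#' @param t0 initial EWMA value.
#' @param params empirical-likelihood tuning constants, see [el_params()].
#' @param mode trace-estimator mode, see [trace_omega_estimates()].
#' @param stop_at_first_alarm truncate the trace at the first exceedance.
#' @param engine `"cpp"` (default) or `"r"` statistic engine.
#' @return An object of class `c("delewma", "spc_chart")` with elements `t`,
#'   `q`, `stat`, `limit`, `lambda`, `D`, `t0`, `first_alarm`, `alarmed`.
#' @examples
#' x <- matrix(rnorm(60 * 46), 60, 46)
#' run_delewma(x, rep(0, 46), lambda = 0.05, D = 10, limit = Inf)
#' @export
run_delewma <- function(stream, mu0, lambda, D, limit = Inf, t0 = 0,
                        params = default_el_params(D, ncol(stream)),
                        mode = c("bias_corrected", "plug_in"),
                        stop_at_first_alarm = FALSE, engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stream <- as.matrix(stream)
  if (nrow(stream) < D)
    stop("stream too short: need at least D = ", D, " rows")
  q <- q_seq(stream, D, mu0, params, mode, engine)
  stat <- ewma_smooth(q, lambda, t0)
  chart_trace("D-ELEWMA", q, stat, limit, lambda, D, t0, stop_at_first_alarm)
}
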