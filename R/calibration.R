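## Monte-Carlo run-length estimation and control-limit search.
##
## Both operations consume a "stat closure": stat_fn(rep_seed, horizon) must
## return the per-step monitoring-statistic sequence of one replication,
## deterministic in rep_seed and prefix-stable in horizon (asking for a longer
## horizon extends the same trajectory).  A bank caches each replication's
## sequence and extends it lazily (doubling) when a candidate limit is not
## crossed within the cached horizon, so every candidate limit is evaluated on
## common random numbers and the alarm rule is pathwise monotone in the limit.

make_stat_bank <- function(stat_fn, reps, seed, init_horizon, cap,
                           lambda = NULL, t0 = 0) {
  bank <- new.env(parent = emptyenv())
  bank$raw <- vector("list", reps)
  bank$smooth <- vector("list", reps)
  bank$len <- integer(reps)
  bank$stat_fn <- stat_fn
  bank$seed <- seed
  bank$cap <- cap
  bank$init_horizon <- min(init_horizon, cap)
  bank$lambda <- lambda
  bank$t0 <- t0
  bank
}

bank_get <- function(bank, r, min_len = bank$init_horizon) {
  min_len <- min(min_len, bank$cap)
  if (bank$len[r] < min_len) {
    new_len <- min(bank$cap, max(min_len, 2L * bank$len[r],
                                 bank$init_horizon))
    raw <- bank$stat_fn(rep_seed(bank$seed, r), new_len)
    if (length(raw) < new_len && length(raw) < bank$cap)
      stop("stat closure returned fewer statistics than requested")
    bank$raw[[r]] <- raw
    bank$smooth[[r]] <- if (is.null(bank$lambda)) raw else
      ewma_smooth(raw, bank$lambda, bank$t0)
    bank$len[r] <- length(raw)
  }
  bank$smooth[[r]]
}

## First exceedance of `limit`, extending the replication up to `cap_eval`.
bank_run_length <- function(bank, r, limit, cap_eval = bank$cap) {
  s <- bank_get(bank, r)
  i <- which(s > limit)[1L]
  while (is.na(i) && bank$len[r] < cap_eval) {
    s <- bank_get(bank, r, min(cap_eval, 2L * bank$len[r]))
    i <- which(s > limit)[1L]
  }
  if (is.na(i)) list(rl = cap_eval, censored = TRUE)
  else list(rl = as.integer(i), censored = FALSE)
}

bank_arl <- function(bank, limit, reps, cap_eval = bank$cap) {
  rl <- integer(reps); cens <- logical(reps)
  for (r in seq_len(reps)) {
    res <- bank_run_length(bank, r, limit, cap_eval)
    rl[r] <- res$rl; cens[r] <- res$censored
  }
  list(rl = rl, arl = mean(rl), censored = sum(cens))
}

rl_summary <- function(rl, censored, limit, seed) {
  structure(list(run_lengths = rl, arl = mean(rl), sdrl = stats::sd(rl),
                 se = stats::sd(rl) / sqrt(length(rl)),
                 censored = censored, reps = length(rl), limit = limit,
                 seed = seed),
            class = "run_length_summary")
}

#' @export
print.run_length_summary <- function(x, ...) {
  cat(sprintf(paste0("Run-length summary (%d replications, limit %.6g):\n",
                     "  ARL = %.4f  SDRL = %.4f  se = %.4f  censored = %d\n"),
              x$reps, x$limit, x$arl, x$sdrl, x$se, x$censored))
  invisible(x)
}

#' Monte-Carlo run-length estimation at a fixed control limit
#'
#' Each replication draws a fresh seeded statistic trajectory from `stat_fn`
#' and records the first step whose (optionally EWMA-smoothed) value exceeds
#' `limit`; trajectories that never alarm within `cap` steps contribute `cap`
#' and are counted as censored.
#'
#' @param stat_fn closure `function(rep_seed, horizon)` returning one
#'   replication's per-step statistic sequence; must be deterministic in
#'   `rep_seed` and prefix-stable in `horizon`.
#' @param limit control limit (alarm when statistic exceeds it).
#' @param reps number of replications (`>= 1`).
#' @param seed base seed; replication `r` uses a seed derived from
#'   `(seed, r)`.
#' @param cap maximum run length per replication (`>= 1`).
#' @param lambda if non-`NULL`, apply EWMA smoothing with this weight to the
#'   raw sequence before thresholding (used by the D-ELEWMA chart, whose raw
#'   statistic is the window Q; the MSEWMA statistic is already smoothed).
#' @param t0 EWMA seed value when `lambda` is used.
#' @param init_horizon initial trajectory length requested per replication
#'   (extended lazily, doubling, up to `cap`).
#' @return An object of class `"run_length_summary"` with `run_lengths`,
#'   `arl`, `sdrl`, `se`, `censored`, `reps`, `limit`, `seed`.
#' @examples
#' unif <- function(s, h) { set.seed(s); runif(h) }
#' estimate_run_lengths(unif, limit = 0.99, reps = 500, seed = 1)
#' @export
estimate_run_lengths <- function(stat_fn, limit, reps, seed, cap = 20000,
                                 lambda = NULL, t0 = 0, init_horizon = NULL) {
  if (reps < 1) stop("'reps' must be at least 1")
  if (cap < 1) stop("'cap' must be at least 1")
  init_horizon <- init_horizon %||% min(cap, 512L)
  bank <- make_stat_bank(stat_fn, reps, seed, init_horizon, cap, lambda, t0)
  rl <- integer(reps); cens <- logical(reps)
  for (r in seq_len(reps)) {
    res <- bank_run_length(bank, r, limit)
    rl[r] <- res$rl; cens[r] <- res$censored
  }
  rl_summary(rl, sum(cens), limit, seed)
}

#' Calibrate a control limit to a nominal in-control ARL
#'
#' Searches for the limit whose Monte-Carlo in-control average run length
#' matches `target_arl0`: an initial guess at the empirical
#' `1 - 1/target_arl0` quantile of the pooled statistic values is expanded
#' geometrically into a bracket, then refined by bisection.  All candidate
#' limits are evaluated on one bank of seeded replications (common random
#' numbers), which makes the estimated ARL exactly non-decreasing in the
#' limit and the search deterministic given `seed`.
#'
#' For EWMA charts whose raw statistic has a nonzero in-control mean (the
#' D-ELEWMA window statistic Q), `t0 = "auto"` seeds the EWMA at the
#' Monte-Carlo mean of the raw statistic, computed from the same bank and
#' reported as `ic_stat_mean`.
#'
#' @inheritParams estimate_run_lengths
#' @param target_arl0 nominal in-control average run length (`> 1`).
#' @param tol accepted |ARL - target| at the returned limit (default
#'   `max(0.5, 0.01 * target_arl0)`).
#' @param t0 `"auto"`, or a number used as EWMA seed (ignored without
#'   `lambda`).
#' @param max_iter maximum bisection iterations.
#' @return An object of class `"spc_calibration"`: `limit`, `achieved_arl0`,
#'   `sdrl`, `reps`, `seed`, `ic_stat_mean`, `t0_used`, `lambda`,
#'   `search_trace` (data frame of evaluated limit/ARL pairs), `censored`,
#'   `target_arl0`.
#' @examples
#' unif <- function(s, h) { set.seed(s); runif(h) }
#' find_control_limit(unif, target_arl0 = 100, reps = 1000, seed = 1)
#' @export
find_control_limit <- function(stat_fn, target_arl0, reps = 2000, seed,
                               cap = 20000, lambda = NULL, t0 = "auto",
                               tol = NULL, init_horizon = NULL,
                               max_iter = 60) {
  if (target_arl0 <= 1) stop("'target_arl0' must exceed 1")
  tol <- tol %||% max(0.5, 0.01 * target_arl0)
  init_horizon <- init_horizon %||% min(cap, ceiling(4 * target_arl0))
  ## Pass 1: raw sequences, in-control statistic mean (EWMA seed).
  bank0 <- make_stat_bank(stat_fn, reps, seed, init_horizon, cap)
  for (r in seq_len(reps)) bank_get(bank0, r)
  ic_stat_mean <- mean(unlist(bank0$raw, use.names = FALSE))
  t0_used <- if (is.null(lambda)) NA_real_ else if (identical(t0, "auto"))
    ic_stat_mean else as.numeric(t0)
  bank <- make_stat_bank(stat_fn, reps, seed, init_horizon, cap, lambda,
                         if (is.na(t0_used)) 0 else t0_used)
  bank$raw <- bank0$raw            # reuse pass-1 draws
  bank$len <- bank0$len
  bank$smooth <- if (is.null(lambda)) bank0$raw else
    lapply(bank0$raw, ewma_smooth, lambda = lambda, t0 = bank$t0)
  rm(bank0)

  pool <- unlist(bank$smooth[seq_len(min(reps, 200L))], use.names = FALSE)
  spread <- stats::sd(pool)
  if (!is.finite(spread) || spread == 0) spread <- 1
  cap_search <- min(cap, ceiling(12 * target_arl0))
  trace_lim <- numeric(0); trace_arl <- numeric(0)
  eval_arl <- function(l, cap_eval = cap_search) {
    res <- bank_arl(bank, l, reps, cap_eval)
    trace_lim <<- c(trace_lim, l); trace_arl <<- c(trace_arl, res$arl)
    res$arl
  }

  l0 <- as.numeric(stats::quantile(pool, 1 - 1 / target_arl0))
  a0 <- eval_arl(l0)
  lo <- hi <- l0; alo <- ahi <- a0
  step <- 0.5 * spread
  iter <- 0
  while (ahi < target_arl0) {
    hi <- hi + step; step <- step * 1.618
    ahi <- eval_arl(hi)
    if ((iter <- iter + 1) > 50)
      stop("bracket failure: ARL0 stays below target up to limit ", hi,
           " (last ARL ", round(ahi, 2), ")")
  }
  step <- 0.5 * spread
  iter <- 0
  while (alo >= target_arl0) {
    lo <- lo - step; step <- step * 1.618
    alo <- eval_arl(lo)
    if ((iter <- iter + 1) > 50)
      stop("bracket failure: ARL0 stays above target down to limit ", lo,
           " (last ARL ", round(alo, 2), ")")
  }

  if (abs(ahi - target_arl0) < abs(alo - target_arl0)) {
    best_l <- hi; best_gap <- abs(ahi - target_arl0)
  } else {
    best_l <- lo; best_gap <- abs(alo - target_arl0)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    am <- eval_arl(mid)
    if (abs(am - target_arl0) < best_gap) {
      best_gap <- abs(am - target_arl0); best_l <- mid
    }
    if (abs(am - target_arl0) <= tol) break
    if (am < target_arl0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-9 * (1 + abs(hi))) break
  }

  final <- bank_arl(bank, best_l, reps, cap)
  if (final$censored > 0.01 * reps)
    stop("more than 1% of calibration runs censored at the returned limit; ",
         "increase 'cap'")
  structure(list(limit = best_l, achieved_arl0 = final$arl,
                 sdrl = stats::sd(final$rl), reps = reps, seed = seed,
                 ic_stat_mean = ic_stat_mean, t0_used = t0_used,
                 lambda = lambda,
                 search_trace = data.frame(limit = trace_lim,
                                           arl = trace_arl),
                 censored = final$censored, target_arl0 = target_arl0),
            class = "spc_calibration")
}

#' @export
print.spc_calibration <- function(x, ...) {
  cat(sprintf(paste0("Control-limit calibration (%d replications):\n",
                     "  limit = %.6g  achieved ARL0 = %.4f ",
                     "(target %.4g)  SDRL = %.4f\n"),
              x$reps, x$limit, x$achieved_arl0, x$target_arl0, x$sdrl))
  if (!is.na(x$t0_used %||% NA))
    cat(sprintf("  EWMA seed t0 = %.6g (IC statistic mean %.6g)\n",
                x$t0_used, x$ic_stat_mean))
  invisible(x)
}
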