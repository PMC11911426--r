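## Chart-specific wrappers binding the generic run-length machinery to the
## synthetic in-control model and the two charts.

## Stat closure for the D-ELEWMA raw window statistic Q under a given stream
## model: a horizon of h monitored steps needs h + D - 1 observations.
delewma_stat_fn <- function(ic, D, params, mode, tau = Inf,
                            shift_coords = integer(0), delta = 0,
                            shift_sd = 1) {
  force(ic); force(D); force(params); force(mode)
  mu0 <- ic$mu0
  function(s, h) {
    x <- sample_stream(ic, stream_spec(h + D - 1, tau = tau,
                                       shift_coords = shift_coords,
                                       delta = delta, shift_sd = shift_sd,
                                       seed = s))
    q_seq(x, D, mu0, params, mode)
  }
}

msewma_stat_fn <- function(ic_model_, ic_transform_, D, lambda, tau = Inf,
                           shift_coords = integer(0), delta = 0,
                           shift_sd = 1) {
  force(ic_model_); force(ic_transform_); force(D); force(lambda)
  function(s, h) {
    x <- sample_stream(ic_model_, stream_spec(h + D - 1, tau = tau,
                                              shift_coords = shift_coords,
                                              delta = delta,
                                              shift_sd = shift_sd, seed = s))
    msewma_stat_seq(x, ic_transform_, D, lambda)$S
  }
}

#' Calibrate the D-ELEWMA upper control limit
#'
#' Monte-Carlo search for the limit L1 attaining the nominal in-control ARL
#' under the given in-control model, via [find_control_limit()].  The EWMA is
#' seeded at the Monte-Carlo in-control mean of the window statistic
#' (`t0 = "auto"`), reported as `ic_stat_mean` and reused by [arl_delewma()].
#'
#' @param ic an [ic_model()]; defaults to the standardized 46-indicator model
#'   built from the packaged reference ranges.
#' @param D sliding-window size.
#' @param lambda EWMA smoothing weight in (0, 1).
#' @param target_arl0 nominal in-control average run length.
#' @param reps Monte-Carlo replications (10,000 reproduces the reference
#'   convention; 2,000 is a practical desk scale).
#' @param seed base seed.
#' @param params empirical-likelihood constants, see [el_params()].
#' @param mode trace-estimator mode.
#' @param cap,tol,t0 passed to [find_control_limit()].
#' @return An `"spc_calibration"` object (with `chart`, `D`, `lambda` fields
#'   added).
#' @export
calibrate_delewma <- function(ic = NULL, D = 10, lambda = 0.05,
                              target_arl0 = 370, reps = 2000, seed = 1,
                              params = NULL,
                              mode = c("bias_corrected", "plug_in"),
                              cap = 20000, tol = NULL, t0 = "auto") {
  mode <- match.arg(mode)
  ic <- ic %||% ic_model_from_ranges(load_reference_ranges())
  params <- params %||% default_el_params(D, ic$p)
  out <- find_control_limit(delewma_stat_fn(ic, D, params, mode),
                            target_arl0 = target_arl0, reps = reps,
                            seed = seed, cap = cap, lambda = lambda, t0 = t0,
                            tol = tol)
  out$chart <- "delewma"; out$D <- D
  out
}

#' Estimate D-ELEWMA run lengths under a stream model
#'
#' With the default `tau = Inf` (no shift) this re-estimates the in-control
#' ARL at a given limit; with `tau = 0` and shift parameters it estimates the
#' out-of-control ARL1 from fully shifted streams.
#'
#' @inheritParams calibrate_delewma
#' @param limit upper control limit L1.
#' @param t0 initial EWMA value (use the calibration's `ic_stat_mean`).
#' @param tau change point (`Inf` = in control, `0` = shifted from the start).
#' @param shift_coords,delta,shift_sd shift model, see [stream_spec()].
#' @return A `"run_length_summary"`.
#' @export
arl_delewma <- function(limit, t0, ic = NULL, D = 10, lambda = 0.05,
                        reps = 2000, seed = 1, tau = Inf,
                        shift_coords = integer(0), delta = 0, shift_sd = 1,
                        params = NULL, mode = c("bias_corrected", "plug_in"),
                        cap = 20000) {
  mode <- match.arg(mode)
  ic <- ic %||% ic_model_from_ranges(load_reference_ranges())
  params <- params %||% default_el_params(D, ic$p)
  sf <- delewma_stat_fn(ic, D, params, mode, tau, shift_coords, delta,
                        shift_sd)
  estimate_run_lengths(sf, limit = limit, reps = reps, seed = seed, cap = cap,
                       lambda = lambda, t0 = t0)
}

#' Calibrate the MSEWMA upper control limit
#'
#' As [calibrate_delewma()], for the windowed spatial-sign MSEWMA chart.  The
#' monitoring statistic S embeds its own EWMA (seeded at the zero vector), so
#' no outer smoothing is applied.
#'
#' @param ic an [ic_model()] for the monitored features; defaults to `p`
#'   independent standard normal coordinates.
#' @param ic_transform an [estimate_ic_transform()]; by default estimated
#'   from `phase1_m` in-control draws (seeded from `seed`).
#' @param p number of monitored features (used when `ic` is NULL).
#' @param phase1_m Phase-I history size for transform estimation.
#' @inheritParams calibrate_delewma
#' @return An `"spc_calibration"` object.
#' @export
calibrate_msewma <- function(ic = NULL, ic_transform = NULL, p = 6, D = 10,
                             lambda = 0.2, target_arl0 = 370, reps = 2000,
                             seed = 1, phase1_m = 1000, cap = 20000,
                             tol = NULL) {
  ic <- ic %||% ic_model(p)
  if (is.null(ic_transform)) {
    hist <- sample_stream(ic, stream_spec(phase1_m,
                                          seed = rep_seed(seed, 0)))
    ic_transform <- estimate_ic_transform(hist)
  }
  out <- find_control_limit(msewma_stat_fn(ic, ic_transform, D, lambda),
                            target_arl0 = target_arl0, reps = reps,
                            seed = seed, cap = cap, lambda = NULL, tol = tol)
  out$chart <- "msewma"; out$D <- D; out$lambda <- lambda
  out$ic_transform <- ic_transform
  out
}

#' Estimate MSEWMA run lengths under a stream model
#'
#' @inheritParams calibrate_msewma
#' @param limit upper control limit L2.
#' @param ic_transform the in-control transform used for monitoring
#'   (required; take it from the calibration result).
#' @param tau,shift_coords,delta,shift_sd shift model, see [stream_spec()].
#' @return A `"run_length_summary"`.
#' @export
arl_msewma <- function(limit, ic_transform, ic = NULL, p = 6, D = 10,
                       lambda = 0.2, reps = 2000, seed = 1, tau = Inf,
                       shift_coords = integer(0), delta = 0, shift_sd = 1,
                       cap = 20000) {
  ic <- ic %||% ic_model(p)
  sf <- msewma_stat_fn(ic, ic_transform, D, lambda, tau, shift_coords, delta,
                       shift_sd)
  estimate_run_lengths(sf, limit = limit, reps = reps, seed = seed, cap = cap)
}
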