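## Simulation-study driver: calibrate each (chart, D, lambda) cell to the
## nominal in-control ARL, then estimate the out-of-control ARL for each
## shift magnitude with fresh seeds.

#' Run the ARL comparison study over a parameter grid
#'
#' For every combination of chart, window size `D` and smoothing weight
#' `lambda`, calibrates the control limit to `target_arl0` on the in-control
#' model, then estimates ARL1/SDRL for each shift magnitude `delta` with
#' fresh replication seeds.  The D-ELEWMA chart monitors all `p` standardized
#' indicators with the shift applied on `coords`; the MSEWMA chart monitors
#' `msewma_p` features of which `msewma_coords` are shifted.
#'
#' @param charts subset of `c("delewma", "msewma")`.
#' @param D window sizes to cover.
#' @param lambda smoothing weights to cover.
#' @param delta shift magnitudes (standard-deviation units).
#' @param p dimension of the D-ELEWMA stream.
#' @param coords shifted coordinates of the D-ELEWMA stream.
#' @param msewma_p number of MSEWMA monitored features.
#' @param msewma_coords shifted coordinates among the monitored features.
#' @param shift_sd standard deviation of the per-observation shift.
#' @param target_arl0 nominal in-control ARL.
#' @param reps_calibration,reps_arl Monte-Carlo replication counts.
#' @param cap run-length cap.
#' @param seed base seed; each grid cell derives its own seed from it and is
#'   reported in the output.
#' @param verbose print one line per completed cell.
#' @return A long-format data frame with one row per
#'   (chart, D, lambda, delta): columns `chart`, `D`, `lambda`, `delta`,
#'   `limit`, `arl0`, `arl1`, `sdrl1`, `se1`, `reps`, `seed`.  Empty grids
#'   give a zero-row frame with the same columns.
#' @export
run_arl_study <- function(charts = c("delewma", "msewma"), D = c(6, 8, 10),
                          lambda = c(0.05, 0.1, 0.2),
                          delta = c(0.3, 0.5, 0.8), p = 46,
                          coords = c(1, 4, 11, 12, 16, 20, 29, 36, 42, 46),
                          msewma_p = 6, msewma_coords = c(1, 4, 6),
                          shift_sd = 1, target_arl0 = 370,
                          reps_calibration = 500, reps_arl = 500,
                          cap = 20000, seed = 1, verbose = FALSE) {
  if (length(charts)) charts <- match.arg(charts, several.ok = TRUE)
  empty <- data.frame(chart = character(0), D = integer(0),
                      lambda = numeric(0), delta = numeric(0),
                      limit = numeric(0), arl0 = numeric(0),
                      arl1 = numeric(0), sdrl1 = numeric(0),
                      se1 = numeric(0), reps = integer(0), seed = numeric(0))
  if (!length(charts) || !length(D) || !length(lambda) || !length(delta))
    return(empty)
  ic_del <- ic_model(p)
  rows <- list()
  cell <- 0L
  for (ch in charts) for (Dv in D) for (lv in lambda) {
    cell <- cell + 1L
    cell_seed <- seed + 1000 * cell
    if (ch == "delewma") {
      cal <- calibrate_delewma(ic = ic_del, D = Dv, lambda = lv,
                               target_arl0 = target_arl0,
                               reps = reps_calibration, seed = cell_seed,
                               cap = cap)
    } else {
      cal <- calibrate_msewma(p = msewma_p, D = Dv, lambda = lv,
                              target_arl0 = target_arl0,
                              reps = reps_calibration, seed = cell_seed,
                              cap = cap)
    }
    for (dv in delta) {
      arl_seed <- cell_seed + match(dv, delta)
      rl <- if (ch == "delewma") {
        arl_delewma(limit = cal$limit, t0 = cal$t0_used, ic = ic_del, D = Dv,
                    lambda = lv, reps = reps_arl, seed = arl_seed, tau = 0,
                    shift_coords = coords, delta = dv, shift_sd = shift_sd,
                    cap = cap)
      } else {
        arl_msewma(limit = cal$limit, ic_transform = cal$ic_transform,
                   p = msewma_p, D = Dv, lambda = lv, reps = reps_arl,
                   seed = arl_seed, tau = 0, shift_coords = msewma_coords,
                   delta = dv, shift_sd = shift_sd, cap = cap)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chart = ch, D = Dv, lambda = lv, delta = dv,
                   limit = cal$limit, arl0 = cal$achieved_arl0,
                   arl1 = rl$arl, sdrl1 = rl$sdrl, se1 = rl$se,
                   reps = reps_arl, seed = arl_seed)
      if (verbose)
        message(sprintf("%s D=%d lambda=%.2f delta=%.1f: ARL1 = %.3f",
                        ch, Dv, lv, dv, rl$arl))
    }
  }
  do.call(rbind, rows)
}
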