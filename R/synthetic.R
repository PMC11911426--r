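## Synthetic biomarker streams: an in-control model built from clinical
## reference ranges, and a change-point shift injector.

#' Load the packaged clinical reference ranges
#'
#' Returns the 46 blood-sample analyte, general-chemical and tumor-marker
#' reference ranges shipped with the package (CA72-4 is not included: it is
#' removed during preprocessing of the motivating data set for excessive
#' missingness).
#'
#' @return A data frame of class `"reference_ranges"` with columns
#'   `abbreviation`, `name`, `sample_type`, `lower`, `upper`, `unit`.
#' @examples
#' rr <- load_reference_ranges()
#' nrow(rr)
#' @export
load_reference_ranges <- function() {
  path <- system.file("extdata", "reference_ranges.csv", package = "hdspc")
  if (!nzchar(path)) stop("packaged reference-range fixture not found")
  rr <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  bad <- which(!is.finite(rr$lower) | !is.finite(rr$upper) |
                 rr$lower >= rr$upper)
  if (length(bad))
    stop("reference-range fixture integrity failure in row(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(rr$abbreviation))
    stop("reference-range fixture has duplicated abbreviations")
  if (nrow(rr) != 46L)
    stop("reference-range fixture must have exactly 46 records, found ",
         nrow(rr))
  class(rr) <- c("reference_ranges", "data.frame")
  rr
}

#' In-control model for stream generation
#'
#' `ic_model()` builds the model directly from per-coordinate means and
#' scales; `ic_model_from_ranges()` derives them from reference ranges:
#' mean = range midpoint and, under the default `"six_sigma"` rule,
#' sd = (upper - lower) / 6 (about 99.7% of draws inside the range);
#' `"four_sigma"` uses width / 4, `"uniform"` draws uniformly on the range.
#' Coordinates are independent.  With `standardized = TRUE` (default) the
#' monitoring scale is the per-coordinate z-score, i.e. `mu0 = 0` and
#' `sigma0 = 1`, which is the scale on which mean shifts of 0.3/0.5/0.8
#' standard deviations are meaningful.
#'
#' @param p dimension.
#' @param mu_raw,sd_raw raw-scale per-coordinate means and scales.
#' @param names optional coordinate names.
#' @param dist `"normal"` or `"uniform"` in-control law.
#' @param standardized monitor on the z-score scale?
#' @param ranges a [load_reference_ranges()] data frame.
#' @param rule `"six_sigma"`, `"four_sigma"` or `"uniform"`.
#' @return An object of class `"ic_model"`: list with `p`, `names`, `mu_raw`,
#'   `sd_raw`, `dist`, `standardized`, and the monitoring-scale `mu0`,
#'   `sigma0`.
#' @examples
#' ic_model_from_ranges(load_reference_ranges())
#' @export
ic_model <- function(p, mu_raw = rep(0, p), sd_raw = rep(1, p), names = NULL,
                     dist = c("normal", "uniform"), standardized = TRUE) {
  dist <- match.arg(dist)
  if (length(mu_raw) != p || length(sd_raw) != p)
    stop("'mu_raw' and 'sd_raw' must have length p")
  if (any(!is.finite(sd_raw)) || any(sd_raw <= 0))
    stop("all scales must be positive")
  mu0 <- if (standardized) rep(0, p) else mu_raw
  sigma0 <- if (standardized) rep(1, p) else sd_raw
  structure(list(p = as.integer(p), names = names, mu_raw = mu_raw,
                 sd_raw = sd_raw, dist = dist,
                 standardized = isTRUE(standardized),
                 mu0 = mu0, sigma0 = sigma0),
            class = "ic_model")
}

#' @rdname ic_model
#' @export
ic_model_from_ranges <- function(ranges,
                                 rule = c("six_sigma", "four_sigma",
                                          "uniform"),
                                 standardized = TRUE) {
  rule <- match.arg(rule)
  if (nrow(ranges) < 1) stop("'ranges' must be non-empty")
  width <- ranges$upper - ranges$lower
  if (any(width <= 0)) stop("degenerate range: lower must be < upper")
  mid <- (ranges$lower + ranges$upper) / 2
  sd_raw <- switch(rule,
                   six_sigma = width / 6,
                   four_sigma = width / 4,
                   uniform = width / sqrt(12))
  ic_model(nrow(ranges), mu_raw = mid, sd_raw = sd_raw,
           names = ranges$abbreviation,
           dist = if (rule == "uniform") "uniform" else "normal",
           standardized = standardized)
}

#' @export
print.ic_model <- function(x, ...) {
  cat(sprintf("In-control model: p = %d, %s coordinates, %s scale\n",
              x$p, x$dist,
              if (x$standardized) "standardized (z-score)" else "raw"))
  invisible(x)
}

#' Stream specification with change point and shift
#'
#' Describes one generated stream: `length` rows, in-control up to the change
#' point `tau` (`tau = 0` means shifted from the first row, `tau = Inf` never
#' shifts), then on each coordinate in `shift_coords` an independent
#' per-observation draw from Normal(`delta`, `shift_sd^2`) is added on the
#' standardized monitoring scale.
#'
#' @param length number of rows.
#' @param tau change-point index in `[0, length]`, or `Inf`.
#' @param shift_coords integer coordinate indices receiving the shift.
#' @param delta mean of the shift distribution.
#' @param shift_sd standard deviation of the shift distribution (default 1;
#'   0 gives a deterministic shift of exactly `delta`).
#' @param seed integer RNG seed.
#' @return list of class `"stream_spec"`.
#' @export
stream_spec <- function(length, tau = Inf, shift_coords = integer(0),
                        delta = 0, shift_sd = 1, seed = 1) {
  if (length < 1) stop("'length' must be at least 1")
  if (!(is.infinite(tau) || (tau >= 0 && tau <= length)))
    stop("'tau' must lie in [0, length] or be Inf")
  if (shift_sd < 0) stop("'shift_sd' must be nonnegative")
  structure(list(length = as.integer(length), tau = tau,
                 shift_coords = as.integer(shift_coords), delta = delta,
                 shift_sd = shift_sd, seed = seed),
            class = "stream_spec")
}

## Offset separating the shift-noise RNG substream from the base stream's.
.SHIFT_SEED_OFFSET <- 1048573

#' Draw a synthetic observation stream
#'
#' Rows are generated in time order from consecutive RNG draws, so two
#' streams sharing a seed agree row-for-row on their common prefix even if
#' their lengths differ.  Shift noise uses a separate RNG substream (derived
#' from `spec$seed`), so a spec with `tau = Inf` or no shift coordinates is
#' bitwise-equal to the pure in-control draw, and changing `tau` only
#' relabels which rows carry the shift.
#'
#' @param ic an [ic_model()].
#' @param spec a [stream_spec()].
#' @return numeric `length x p` matrix (column names from the model, if any).
#' @examples
#' ic <- ic_model(4)
#' x <- sample_stream(ic, stream_spec(20, tau = 10, shift_coords = 1:2,
#'                                    delta = 0.8, seed = 7))
#' @export
sample_stream <- function(ic, spec) {
  stopifnot(inherits(ic, "ic_model"), inherits(spec, "stream_spec"))
  p <- ic$p
  if (length(spec$shift_coords) &&
      (min(spec$shift_coords) < 1 || max(spec$shift_coords) > p))
    stop("'shift_coords' out of range 1..p")
  T_ <- spec$length
  set.seed(spec$seed)
  Z <- if (ic$dist == "normal") {
    matrix(stats::rnorm(T_ * p), nrow = T_, byrow = TRUE)
  } else {
    matrix((stats::runif(T_ * p) - 0.5) * sqrt(12), nrow = T_, byrow = TRUE)
  }
  X <- if (ic$standardized) Z else
    sweep(Z, 2, ic$sd_raw, `*`) + matrix(ic$mu_raw, T_, p, byrow = TRUE)
  shifted_rows <- if (is.infinite(spec$tau) || spec$tau >= T_) integer(0) else
    seq.int(spec$tau + 1, T_)
  if (length(spec$shift_coords) && length(shifted_rows)) {
    set.seed((spec$seed + .SHIFT_SEED_OFFSET) %% 2147483647)
    ns <- length(shifted_rows); nc <- length(spec$shift_coords)
    shift <- matrix(stats::rnorm(ns * nc, mean = spec$delta,
                                 sd = spec$shift_sd),
                    nrow = ns, byrow = TRUE)
    scale <- if (ic$standardized) rep(1, nc) else ic$sd_raw[spec$shift_coords]
    X[shifted_rows, spec$shift_coords] <-
      X[shifted_rows, spec$shift_coords] +
      sweep(shift, 2, scale, `*`)
  }
  if (!is.null(ic$names)) colnames(X) <- ic$names
  X
}
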