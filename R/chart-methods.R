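## S3 methods for chart traces.

#' @export
print.spc_chart <- function(x, ...) {
  cat(sprintf("%s control chart (D = %d, lambda = %g)\n", x$chart, x$D,
              x$lambda))
  cat(sprintf("  %d monitored step(s), upper limit %.6g\n", length(x$stat),
              x$limit))
  if (x$alarmed)
    cat(sprintf("  first alarm at step %d (stat = %.6g)\n", x$first_alarm,
                x$stat[x$first_alarm]))
  else cat("  no alarm\n")
  invisible(x)
}

#' @export
summary.spc_chart <- function(object, ...) {
  cat(sprintf("%s control chart\n", object$chart))
  cat(sprintf("  window D = %d, lambda = %g, limit = %.6g, t0 = %.6g\n",
              object$D, object$lambda, object$limit, object$t0))
  cat(sprintf("  steps: %d, exceedances: %d, first alarm: %s\n",
              length(object$stat), sum(object$stat > object$limit),
              if (object$alarmed) object$first_alarm else "none"))
  print(summary(object$stat))
  invisible(object)
}

#' Plot a control-chart trace
#'
#' Base-graphics trace of the monitoring statistic against the monitored
#' step, with the upper control limit and alarms marked.
#'
#' @param x an `"spc_chart"` object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.spc_chart <- function(x, ...) {
  plot(x$t, x$stat, type = "b", pch = 20, cex = 0.6,
       xlab = "monitored step", ylab = "monitoring statistic",
       main = sprintf("%s chart (D = %d, lambda = %g)", x$chart, x$D,
                      x$lambda), ...)
  if (is.finite(x$limit)) abline(h = x$limit, lty = 2, col = "red3")
  bad <- x$stat > x$limit
  if (any(bad)) points(x$t[bad], x$stat[bad], pch = 19, col = "red3")
  invisible(x)
}

#' Export a chart trace as a data frame
#'
#' @param x an `"spc_chart"` object.
#' @param row.names,optional,... as in [as.data.frame()].
#' @return data frame with columns `t`, `q`, `stat`, `limit`, `alarm`.
#' @export
as.data.frame.spc_chart <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(t = x$t, q = x$q, stat = x$stat, limit = x$limit,
             alarm = x$stat > x$limit, row.names = row.names)
}
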