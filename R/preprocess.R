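## Data preparation: missingness filtering with mean imputation, Jarque-Bera
## normality screening, and group mean-difference profiling.

#' Drop high-missingness columns and mean-impute the rest
#'
#' Columns whose missing fraction exceeds `drop_threshold` are removed;
#' remaining missing entries are replaced by the column mean of the observed
#' values.  The operation is idempotent.
#'
#' @param table data frame or matrix of numeric columns (NAs mark missing
#'   entries).
#' @param drop_threshold drop a column when its missing fraction exceeds
#'   this, in (0, 1].
#' @return list with `data` (cleaned data frame), `dropped` (character vector
#'   of removed columns) and `n_imputed` (count of imputed cells).
#' @examples
#' d <- data.frame(a = c(1, NA, 3), b = c(NA, NA, 5))
#' filter_and_impute(d, drop_threshold = 0.5)
#' @export
filter_and_impute <- function(table, drop_threshold = 0.5) {
  if (drop_threshold <= 0 || drop_threshold > 1)
    stop("'drop_threshold' must lie in (0, 1]")
  table <- as.data.frame(table)
  not_num <- !vapply(table, is.numeric, logical(1))
  if (any(not_num))
    stop("non-numeric column(s): ", paste(names(table)[not_num],
                                          collapse = ", "))
  miss <- vapply(table, function(col) mean(is.na(col)), numeric(1))
  dropped <- names(table)[miss > drop_threshold]
  kept <- table[, miss <= drop_threshold, drop = FALSE]
  n_imputed <- 0L
  for (j in seq_along(kept)) {
    na <- is.na(kept[[j]])
    if (any(na)) {
      kept[[j]][na] <- mean(kept[[j]][!na])
      n_imputed <- n_imputed + sum(na)
    }
  }
  list(data = kept, dropped = dropped, n_imputed = n_imputed)
}

#' Jarque-Bera normality test
#'
#' `JB = m (skewness^2 / 6 + (excess kurtosis)^2 / 24)`, referred to the
#' chi-square distribution with 2 degrees of freedom.  Sample skewness and
#' kurtosis use population central moments (divisor `m`); kurtosis is excess
#' (`K - 3`).  The asymptotic reference distribution is unreliable for small
#' samples; at least 8 observations are required and several dozen are
#' advisable.
#'
#' @param x numeric vector, `length(x) >= 8`, nonzero variance.
#' @return list with `jb_stat` and `p_value`.
#' @examples
#' jarque_bera(rnorm(100))
#' @export
jarque_bera <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  m <- length(x)
  if (m < 8) stop("need at least 8 observations")
  c1 <- x - mean(x)
  m2 <- mean(c1^2)
  if (m2 <= .Machine$double.eps * mean(x^2))
    stop("degenerate sample: zero variance")
  skew <- mean(c1^3) / m2^1.5
  exk <- mean(c1^4) / m2^2 - 3
  jb <- m * (skew^2 / 6 + exk^2 / 24)
  list(jb_stat = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Jarque-Bera screening of every column
#'
#' @param table data frame or matrix of numeric columns.
#' @param alpha rejection level for the normality null.
#' @return data frame with one row per column: `column`, `jb_stat`,
#'   `p_value`, `reject` (`p_value < alpha`).
#' @export
normality_screen <- function(table, alpha = 0.05) {
  table <- as.data.frame(table)
  res <- lapply(table, jarque_bera)
  data.frame(column = names(table),
             jb_stat = vapply(res, `[[`, numeric(1), "jb_stat"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             reject = vapply(res, function(r) r$p_value < alpha, logical(1)),
             row.names = NULL)
}

#' Per-column mean difference between two groups
#'
#' `colMeans(b) - colMeans(a)`, optionally on the z-score scale of group `a`
#' (divided by `a`'s column standard deviations).  Used to locate candidate
#' shifted coordinates when contrasting a reference group with a case group.
#'
#' @param a,b data frames or matrices with identical column names in the same
#'   order.
#' @param standardize divide by `a`'s column standard deviations.
#' @return named numeric vector of per-column differences.
#' @export
group_mean_difference <- function(a, b, standardize = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b) || !identical(colnames(a), colnames(b)))
    stop("'a' and 'b' must share the same columns in the same order")
  d <- colMeans(b, na.rm = TRUE) - colMeans(a, na.rm = TRUE)
  if (standardize) d <- d / apply(a, 2, stats::sd, na.rm = TRUE)
  d
}
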