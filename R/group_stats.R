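#' One-sample and paired t-tests
#'
#' Thin wrappers around the classical t-test returning a flat result
#' container used throughout the group-level analyses.
#'
#' @param x numeric vector (for the paired test, the first condition).
#' @param mu null value (one-sample).
#' @return list of class `test_result`: statistic, df, p, direction
#'   (sign of the effect), n, mean.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) {
    return(structure(list(statistic = NA_real_, df = 0, p = NA_real_,
                          direction = sign(mean(x) - mu), n = length(x),
                          mean = mean(x), degenerate = TRUE),
                     class = "test_result"))
  }
  if (stats::sd(x) == 0) {
    d <- mean(x) - mu
    return(structure(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                          df = length(x) - 1,
                          p = if (d == 0) 1 else 0, direction = sign(d),
                          n = length(x), mean = mean(x), degenerate = TRUE),
                     class = "test_result"))
  }
  tt <- stats::t.test(x, mu = mu)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, direction = sign(mean(x) - mu),
                 n = length(x), mean = mean(x), degenerate = FALSE),
            class = "test_result")
}

#' @rdname one_sample_t
#' @param y second condition (paired).
#' @export
paired_t <- function(x, y) {
  one_sample_t(x - y, mu = 0)
}

#' @export
print.test_result <- function(x, ...) {
  if (length(x$df) == 2)
    cat(sprintf("F_%g,%g = %.3f, p = %.4g (n = %d)\n",
                x$df[1], x$df[2], x$statistic, x$p, x$n))
  else
    cat(sprintf("T_%g = %.3f, p = %.4g (n = %d)\n",
                x$df, x$statistic, x$p, x$n))
  invisible(x)
}

#' 2x2 repeated-measures interaction
#'
#' The interaction of a 2x2 within-participant design is a single degree of
#' freedom: the paired t-test on the difference-of-differences contrast
#' `(c1 - c2) - (c3 - c4)`; F = t^2 with df = (1, n-1).
#'
#' @param cells matrix participants x 4 (cell order c11, c12, c21, c22,
#'   e.g. from [accuracy_by_condition()]).
#' @return list of class `test_result` with `statistic` = F, `df` =
#'   c(1, n-1), plus the underlying contrast t in `t`.
#' @export
rm_anova_2x2 <- function(cells) {
  stopifnot(ncol(cells) == 4)
  contrast <- (cells[, 1] - cells[, 2]) - (cells[, 3] - cells[, 4])
  tt <- one_sample_t(contrast)
  structure(list(statistic = tt$statistic^2, df = c(1, tt$df), p = tt$p,
                 direction = tt$direction, n = tt$n, t = tt$statistic,
                 mean = mean(contrast), degenerate = tt$degenerate),
            class = "test_result")
}

#' JZS Bayes factor for a one-sample (or paired-difference) t-test
#'
#' Evidence for an effect (H1: standardised effect delta ~ Cauchy(0, r))
#' against the null (delta = 0), computed by integrating the noncentral-t
#' likelihood over the Cauchy prior. Values below 1/3 are conventionally
#' read as evidence for the null.
#'
#' @param x numeric vector of differences.
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @return list: `bf10`, `bf01`, `t`, `df`, `n`.
#' @export
bf_null_ttest <- function(x, r = sqrt(2) / 2) {
  n <- length(x)
  tval <- mean(x) / (stats::sd(x) / sqrt(n))
  bf_from_t(tval, n, r = r)
}

#' @rdname bf_null_ttest
#' @param tval observed t statistic.
#' @param n sample size (df = n - 1).
#' @export
bf_from_t <- function(tval, n, r = sqrt(2) / 2) {
  df <- n - 1
  # dt(ncp=) warns about the last digits of precision; harmless here
  m1 <- suppressWarnings(stats::integrate(function(d)
    stats::dt(tval, df, ncp = d * sqrt(n)) * stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-8)$value)
  bf10 <- m1 / stats::dt(tval, df)
  list(bf10 = bf10, bf01 = 1 / bf10, t = tval, df = df, n = n)
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors.
#' @return list: `r`, `p`, `df`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}
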