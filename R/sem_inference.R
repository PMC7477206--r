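#' Semi-partial correlation
#'
#' Correlation between an outcome and the residual of a predictor after
#' least-squares removal of one or more control variables (the control is
#' removed from the predictor only, not from the outcome).
#'
#' @param y Outcome vector.
#' @param x Predictor vector.
#' @param control Vector, matrix or data frame of control variables.
#' @return List with `r`, `p` (two-sided, from the t distribution with
#'   n - 2 df) and `n`.
#' @export
semi_partial_corr <- function(y, x, control) {
  control <- as.matrix(control)
  keep <- stats::complete.cases(y, x, control)
  y <- y[keep]; x <- x[keep]
  control <- control[keep, , drop = FALSE]
  n <- length(y)
  if (n < 4) stop("semi_partial_corr: need at least 4 complete cases")
  x_res <- residualize_confounds(matrix(x, ncol = 1), control)[, 1]
  if (stats::var(x_res) < 1e-12 * max(stats::var(x), 1e-12))
    stop("semi_partial_corr: predictor is collinear with the controls")
  r <- stats::cor(y, x_res)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE), n = n)
}

#' Bootstrap mediation analysis
#'
#' Single-mediator linear mediation: `a` is the x -> m coefficient, `b` the
#' m -> y coefficient given x, `c_total` the total x -> y effect, `c_direct`
#' the direct effect given m, and the indirect effect is `a * b`. Confidence
#' intervals are nonparametric case-resampling percentile bootstrap
#' intervals. On complete data `c_total = c_direct + indirect` holds exactly.
#'
#' @param x,m,y Aligned numeric vectors: exposure, mediator, outcome.
#' @param n_boot Bootstrap iterations (10,000 by default).
#' @param seed RNG seed (mandatory, for reproducible intervals).
#' @param conf_level Confidence level of the percentile intervals.
#' @param standardized Z-score x, m, y first, so coefficients are
#'   standardised betas.
#' @return Object of class `mediation_result` with coefficients, the
#'   bootstrap percentile CIs, `n_boot` and `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 10000, seed, conf_level = 0.95,
                    standardized = TRUE) {
  if (missing(seed)) stop("mediate: a seed is required")
  keep <- stats::complete.cases(x, m, y)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("mediate: too few complete cases")
  if (stats::var(x) <= 0 || stats::var(m) <= 0 || stats::var(y) <= 0)
    stop("mediate: degenerate variance in x, m or y")
  if (standardized) {
    x <- as.vector(scale(x)); m <- as.vector(scale(m))
    y <- as.vector(scale(y))
  }

  paths <- function(x, m, y) {
    sxx <- stats::var(x); sxm <- stats::cov(x, m); sxy <- stats::cov(x, y)
    smm <- stats::var(m); smy <- stats::cov(m, y)
    a <- sxm / sxx
    det2 <- sxx * smm - sxm^2
    if (det2 <= 1e-12 * sxx * smm)
      return(c(a = NA_real_, b = NA_real_, c_direct = NA_real_,
               c_total = NA_real_))
    c_direct <- (sxy * smm - sxm * smy) / det2
    b <- (sxx * smy - sxm * sxy) / det2
    c_total <- sxy / sxx
    c(a = a, b = b, c_direct = c_direct, c_total = c_total)
  }

  est <- paths(x, m, y)
  if (anyNA(est))
    stop("mediate: mediator is collinear with the exposure; ",
         "direct and indirect effects are not identified")
  indirect <- est[["a"]] * est[["b"]]

  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 5,
                  dimnames = list(NULL, c("a", "b", "c_direct", "c_total",
                                          "indirect")))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- paths(x[idx], m[idx], y[idx])
    draws[i, ] <- c(pb, pb[["a"]] * pb[["b"]])
  }
  alpha <- 1 - conf_level
  ci <- apply(draws, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)

  out <- list(a = est[["a"]], b = est[["b"]],
              c_direct = est[["c_direct"]], c_total = est[["c_total"]],
              indirect = indirect,
              boot_ci = ci, conf_level = conf_level,
              n = n, n_boot = n_boot, seed = seed)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Mediation (", x$n, " cases, ", x$n_boot, " bootstrap draws)\n",
      sep = "")
  cat(sprintf("  a (x->m)        = %.*f\n", digits, x$a))
  cat(sprintf("  b (m->y | x)    = %.*f\n", digits, x$b))
  cat(sprintf("  c total (x->y)  = %.*f\n", digits, x$c_total))
  cat(sprintf("  c direct        = %.*f\n", digits, x$c_direct))
  ci <- x$boot_ci[, "indirect"]
  cat(sprintf("  indirect (a*b)  = %.*f  [%.*f, %.*f] %d%% percentile CI\n",
              digits, x$indirect, digits, ci[1], digits, ci[2],
              round(100 * x$conf_level)))
  invisible(x)
}
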