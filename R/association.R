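#' Correlation and regression inference
#'
#' Pearson correlations with Fisher-z confidence intervals, comparison of
#' two correlation coefficients after Fisher's r-to-z transformation, and
#' multiple regression with standardised betas and variance-inflation
#' diagnostics.
#'
#' @name association
NULL

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Aligned numeric vectors (n > 3 complete pairs).
#' @param alpha Two-sided significance level for the interval.
#' @return List with `r`, `ci` (back-transformed Fisher interval with
#'   standard error `1/sqrt(n-3)`), `p` (from the t statistic
#'   `r*sqrt(n-2)/sqrt(1-r^2)`) and `n`.
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n <= 3) stop("pearson_ci: need more than 3 complete pairs")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("pearson_ci: zero variance")
  r <- stats::cor(x, y)
  z <- atanh(r)
  zcrit <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  list(r = r, ci = ci, p = p, n = n)
}

#' Compare two correlations via Fisher's r-to-z transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return List with the Fisher transforms `z1`, `z2`, the test statistic
#'   `z_stat` and `p_two_sided`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("fisher_rz_compare: |r| must be below 1")
  if (n1 <= 3 || n2 <= 3) stop("fisher_rz_compare: need n > 3 in each group")
  z1 <- atanh(r1); z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z_stat <- (z1 - z2) / se
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z1 = z1, z2 = z2,
       z_stat = z_stat,
       p_two_sided = 2 * stats::pnorm(abs(z_stat), lower.tail = FALSE))
}

#' Multiple regression with standardised betas and VIF diagnostics
#'
#' Ordinary least squares of `y` on the predictor table (an intercept is
#' added). Standardised betas come from refitting on z-scored variables;
#' variance inflation factors are `1/(1 - R^2_j)` from each predictor's
#' auxiliary regression on the others. Cases with any missing value are
#' dropped (listwise).
#'
#' @param y Outcome vector.
#' @param X Data frame or matrix of predictors (numeric).
#' @return Object of class `regression_table`: per-predictor `beta`, `se`,
#'   `std_beta`, `t`, `p`, `vif`; plus `F`, `df_num`, `df_den`, `r_squared`,
#'   `n`.
#' @export
fit_regression <- function(y, X) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop("fit_regression: too few complete cases")

  Xm <- as.matrix(X)
  qrX <- qr(cbind(1, Xm))
  if (qrX$rank < k + 1) {
    aux <- qr(Xm)
    bad <- colnames(Xm)[aux$pivot[seq.int(aux$rank + 1L, k)]]
    stop("fit_regression: rank-deficient design; collinear predictor(s): ",
         paste(bad, collapse = ", "))
  }

  dat <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients

  datz <- as.data.frame(lapply(dat, function(col) as.vector(scale(col))))
  fitz <- stats::lm(y ~ ., data = datz)
  std_beta <- stats::coef(fitz)[-1]

  vif <- if (k > 1) car::vif(fit) else stats::setNames(1, names(X))

  table <- data.frame(
    predictor = rownames(coefs)[-1],
    beta = coefs[-1, 1], se = coefs[-1, 2],
    std_beta = unname(std_beta[rownames(coefs)[-1]]),
    t = coefs[-1, 3], p = coefs[-1, 4],
    vif = unname(vif[rownames(coefs)[-1]]),
    row.names = NULL
  )
  out <- list(
    table = table,
    intercept = coefs[1, ],
    F = unname(sm$fstatistic["value"]),
    df_num = unname(sm$fstatistic["numdf"]),
    df_den = unname(sm$fstatistic["dendf"]),
    r_squared = sm$r.squared,
    p_overall = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                          sm$fstatistic["dendf"], lower.tail = FALSE),
    n = n
  )
  class(out) <- "regression_table"
  out
}

#' @export
print.regression_table <- function(x, digits = 3, ...) {
  cat(sprintf("OLS: F(%d, %d) = %.2f, R^2 = %.3f, n = %d\n",
              x$df_num, x$df_den, x$F, x$r_squared, x$n))
  print(x$table, digits = digits)
  invisible(x)
}

#' Write a regression table (TSV) and summary (JSON)
#'
#' @param reg A [fit_regression()] result.
#' @param tsv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, `reg`.
#' @export
write_regression <- function(reg, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(reg$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(F = reg$F, df_num = reg$df_num, df_den = reg$df_den,
           r_squared = reg$r_squared, p = reg$p_overall, n = reg$n),
      json_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(reg)
}
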