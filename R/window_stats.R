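#' Model-free sliding-window association curves
#'
#' Conditional-mean curves of an outcome along a predictor without assuming
#' linearity: overlapping quantile windows (each holding a fixed fraction of
#' participants) slide along the predictor distribution; fixed-width bins
#' and Gaussian smoothing of the resulting curve are also provided, plus
#' quantile-bin age residualisation for deconfounding.
#'
#' @name window_stats
NULL

new_window_curve <- function(centers, means, sems, counts, param) {
  out <- data.frame(center = centers, mean = means, sem = sems,
                    count = counts)
  attr(out, "param") <- param
  class(out) <- c("window_curve", "data.frame")
  out
}

#' Sliding quantile-window curve
#'
#' Participants are sorted by `x` (ties broken by original position); a
#' window containing `frac` of them slides along the distribution in steps
#' of `step_quantile`. Defaults (10% windows, 1-percentile steps) give 91
#' windows. Each window reports the median `x` (center), the mean of `y`,
#' its standard error (SD/sqrt(count)) and the window size.
#'
#' @param x,y Aligned numeric vectors.
#' @param frac Fraction of participants per window.
#' @param step_quantile Quantile step between window starts.
#' @return A `window_curve` data frame: `center`, `mean`, `sem`, `count`.
#' @export
sliding_window_curve <- function(x, y, frac = 0.10, step_quantile = 0.01) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < ceiling(1 / frac))
    stop("sliding_window_curve: need at least ", ceiling(1 / frac),
         " observations for frac = ", frac)
  ord <- order(x, seq_along(x))   # stable tie-break on original index
  xs <- x[ord]; ys <- y[ord]
  w <- max(1L, round(frac * n))
  starts_q <- seq(0, 1 - frac, by = step_quantile)
  lo <- pmin(floor(starts_q * n) + 1L, n - w + 1L)
  lo <- pmax(lo, 1L)
  centers <- means <- sems <- numeric(length(lo))
  for (k in seq_along(lo)) {
    idx <- lo[k]:(lo[k] + w - 1L)
    centers[k] <- stats::median(xs[idx])
    means[k] <- mean(ys[idx])
    sems[k] <- stats::sd(ys[idx]) / sqrt(w)
  }
  new_window_curve(centers, means, sems, rep(w, length(lo)),
                   list(frac = frac, step_quantile = step_quantile, n = n))
}

#' Gaussian smoothing of a curve
#'
#' Moving weighted average with Gaussian weights of standard deviation
#' `kernel` index units, renormalised at the edges so the weights always sum
#' to one (so a constant series is unchanged and no mass is lost).
#'
#' @param values Numeric series (e.g. window means).
#' @param kernel Kernel SD in index units.
#' @return Smoothed series of the same length.
#' @export
gaussian_smooth <- function(values, kernel = 10) {
  if (kernel <= 0) stop("gaussian_smooth: kernel must be positive")
  n <- length(values)
  if (n == 0L) return(values)
  half <- min(n - 1L, ceiling(4 * kernel))
  offs <- -half:half
  wts <- stats::dnorm(offs, sd = kernel)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    out[i] <- sum(wts[ok] * values[j[ok]]) / sum(wts[ok])
  }
  out
}

#' Fixed-width bin curve
#'
#' Bins `x` into consecutive intervals of `width` starting at the largest
#' multiple of `width` at or below `min(x)` (configurable via `origin`),
#' reporting per-bin mean, SEM and count. Empty bins are flagged and
#' excluded from the curve rows.
#'
#' @param x,y Aligned numeric vectors.
#' @param n_bins Number of bins.
#' @param width Bin width in `x` units (16 mmHg for systolic pressure).
#' @param origin Left edge of the first bin; defaults to `min(x)` floored to
#'   a multiple of `width`.
#' @return A `window_curve` data frame with additional column `bin`;
#'   attribute `empty_bins` lists flagged empty bin indices.
#' @export
fixed_bin_curve <- function(x, y, n_bins = 10, width = 16, origin = NULL) {
  if (width <= 0) stop("fixed_bin_curve: width must be positive")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (is.null(origin)) origin <- floor(min(x) / width) * width
  breaks <- origin + width * (0:n_bins)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  bin[bin < 1L | bin > n_bins] <- NA
  rows <- lapply(seq_len(n_bins), function(b) {
    yb <- y[!is.na(bin) & bin == b]
    if (!length(yb)) return(NULL)
    data.frame(bin = b, center = origin + width * (b - 0.5),
               mean = mean(yb),
               sem = if (length(yb) > 1) stats::sd(yb) / sqrt(length(yb))
                     else NA_real_,
               count = length(yb))
  })
  empty <- which(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin = integer(0), center = numeric(0),
                      mean = numeric(0), sem = numeric(0), count = integer(0))
  attr(out, "empty_bins") <- empty
  attr(out, "param") <- list(n_bins = n_bins, width = width, origin = origin)
  class(out) <- c("window_curve", "data.frame")
  out
}

#' Age-quantile-bin residuals
#'
#' Assigns participants to `n_bins` age-quantile bins (equal counts, ties
#' broken by original position) and removes each bin's mean from `v`. The
#' result has mean zero within every bin, removing the (possibly non-linear)
#' age trend from `v`.
#'
#' @param v Variable to residualise.
#' @param age Age vector, aligned with `v`.
#' @param n_bins Number of quantile bins.
#' @return Residual vector with attribute `bin` (the bin assignments;
#'   `NA` entries of `v`/`age` give `NA` residuals).
#' @export
age_quantile_residuals <- function(v, age, n_bins = 10) {
  if (length(v) != length(age))
    stop("age_quantile_residuals: v and age must be aligned")
  keep <- which(stats::complete.cases(v, age))
  n <- length(keep)
  if (n < n_bins) stop("age_quantile_residuals: fewer cases than bins")
  rk <- rank(age[keep], ties.method = "first")
  bin_k <- ceiling(rk * n_bins / n)
  res <- rep(NA_real_, length(v))
  bins <- rep(NA_integer_, length(v))
  bins[keep] <- bin_k
  for (b in unique(bin_k)) {
    idx <- keep[bin_k == b]
    res[idx] <- v[idx] - mean(v[idx])
  }
  attr(res, "bin") <- bins
  res
}

#' Write a curve table as TSV
#'
#' @param curve A `window_curve` (from [sliding_window_curve()] or
#'   [fixed_bin_curve()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
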