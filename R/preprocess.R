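#' Trial filtering and robust normalisation
#'
#' Reaction-time trials outside the valid response window are removed before
#' averaging; white-matter-hyperintensity volume is cube-root transformed;
#' all model variables are median/MAD normalised; imaging phenotypes can be
#' residualised against confounds.
#'
#' @name preprocess
NULL

#' Filter reaction-time trials to the valid response window
#'
#' Anticipatory responses (below 50 ms) and responses after stimulus offset
#' (above 2000 ms) are removed; both boundaries are kept (inclusive window).
#'
#' @param trials Numeric vector of reaction times, ms.
#' @param lower,upper Window boundaries in ms, inclusive.
#' @return The surviving trials in their original order (possibly empty).
#' @export
filter_rt_trials <- function(trials, lower = 50, upper = 2000) {
  trials <- trials[!is.na(trials)]
  trials[trials >= lower & trials <= upper]
}

#' Mean reaction time over surviving trials
#'
#' @param trials Numeric vector of already-filtered reaction times, ms.
#' @return Arithmetic mean, ms.
#' @export
mean_rt <- function(trials) {
  if (length(trials) == 0L)
    stop("mean_rt: no trials survive filtering; cognitive score missing")
  mean(trials)
}

#' Median/MAD normalisation
#'
#' Centres at the median and scales by the median absolute deviation times
#' the normal-consistency constant 1.4826 (so the scale estimates an SD for
#' Gaussian data). Missing values are ignored when estimating centre and
#' scale and preserved in the output.
#'
#' @param x Numeric vector with positive MAD.
#' @param constant Consistency constant; set to 1 for the raw MAD.
#' @param name Column name used in error messages.
#' @return Normalised vector with attributes `center` and `scale`.
#' @export
mad_normalize <- function(x, constant = 1.4826, name = deparse(substitute(x))) {
  ctr <- stats::median(x, na.rm = TRUE)
  scl <- stats::mad(x, constant = constant, na.rm = TRUE)
  if (!is.finite(scl) || scl <= 0)
    stop("mad_normalize: zero/degenerate MAD in column '", name, "'")
  out <- (x - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Cube-root transform for WMH volume
#'
#' Total white-matter-hyperintensity load is heavily right-skewed; the cube
#' root brings it close to symmetry.
#'
#' @param v Volume in cubic mm, non-negative.
#' @return `v^(1/3)`.
#' @export
cube_root_wmh <- function(v) {
  if (any(v < 0, na.rm = TRUE))
    stop("cube_root_wmh: negative volume")
  v^(1 / 3)
}

#' Residualise variables against confounds
#'
#' Least-squares removal of confound columns (plus an intercept) from each
#' column of `Y`. Used for head-size and scan-date confounds of imaging
#' phenotypes.
#'
#' @param Y Numeric matrix (or data frame) of variables, rows = cases.
#' @param C Numeric matrix of confounds, same row order.
#' @return Matrix of residuals, orthogonal to every confound column and to
#'   the intercept.
#' @export
residualize_confounds <- function(Y, C) {
  Y <- as.matrix(Y); C <- as.matrix(C)
  if (nrow(Y) != nrow(C))
    stop("residualize_confounds: row mismatch between Y and C")
  X <- cbind(`(Intercept)` = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("residualize_confounds: confound matrix is rank deficient (",
         paste(drop, collapse = ", "), ")")
  }
  Y - X %*% qr.coef(qrX, Y)
}

#' Assemble the analysis table from a raw cohort
#'
#' Applies the full preprocessing chain: per-participant mean filtered
#' reaction time, cube-root WMH volume, orientation flips so that larger
#' values mean better function/integrity (reaction time and error counts are
#' negated, as is orientation dispersion), then median/MAD normalisation of
#' every model variable. The resulting columns are the variables the default
#' structural model expects: `age`, `cvr`, `wmh`, the six frontoparietal
#' grey-matter volumes (`ag`, `prc`, `cg`, `sfg`, `fp`, `mtg`), the
#' superior-longitudinal-fasciculus NODDI indicators (`icvf`, `od`) and the
#' cognitive scores (`rt`, `pairs`).
#'
#' @param cohort Raw cohort data frame (see [generate_cohort()] for the
#'   column dictionary).
#' @param flip Logical; negate `rt`, `pairs` and `od` so higher = better
#'   (default). `FALSE` keeps the recorded orientation.
#' @param rt_window Valid reaction-time window in ms, see
#'   [filter_rt_trials()].
#' @return Data frame of normalised analysis variables, with attribute
#'   `normalization` (per-column centre/scale/transform) suitable for
#'   [write_normalization_sidecar()].
#' @export
prepare_analysis_table <- function(cohort, flip = TRUE,
                                   rt_window = c(50, 2000)) {
  rt_cols <- grep("^rt_trial_", names(cohort), value = TRUE)
  if (length(rt_cols)) {
    trials <- as.matrix(cohort[rt_cols])
    trials[trials < rt_window[1] | trials > rt_window[2]] <- NA
    kept <- rowSums(!is.na(trials))
    rt_mean <- rowMeans(trials, na.rm = TRUE)
    rt_mean[kept == 0L] <- NA
  } else {
    rt_mean <- cohort$rt_mean
  }

  cvr <- score_cohort(cohort)$total

  raw <- data.frame(
    age   = cohort$age_at_scan,
    cvr   = cvr,
    wmh   = cube_root_wmh(cohort$wmh_mm3),
    ag    = cohort$vol_ag,
    prc   = cohort$vol_prc,
    cg    = cohort$vol_cg,
    sfg   = cohort$vol_sfg,
    fp    = cohort$vol_fp,
    mtg   = cohort$vol_mtg,
    icvf  = cohort$slf_icvf,
    od    = cohort$slf_od,
    rt    = rt_mean,
    pairs = cohort$pairs_errors
  )
  transforms <- c(wmh = "cube_root", rt = "mean_filtered_trials")
  if (flip) {
    for (v in c("rt", "pairs", "od")) raw[[v]] <- -raw[[v]]
    transforms <- c(transforms,
                    rt = "negated", pairs = "negated", od = "negated")
  }

  norm <- lapply(names(raw), function(v) mad_normalize(raw[[v]], name = v))
  out <- as.data.frame(lapply(norm, as.vector))
  names(out) <- names(raw)
  attr(out, "normalization") <- data.frame(
    variable = names(raw),
    center = vapply(norm, attr, numeric(1), "center"),
    scale = vapply(norm, attr, numeric(1), "scale"),
    transform = vapply(names(raw), function(v)
      paste(transforms[names(transforms) == v], collapse = "+"),
      character(1))
  )
  out
}

#' Write the normalisation sidecar
#'
#' Records per-variable centres, scales and transforms as JSON so a
#' normalised table can be reproduced or inverted.
#'
#' @param table Output of [prepare_analysis_table()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normalization_sidecar <- function(table, path) {
  sidecar <- attr(table, "normalization")
  if (is.null(sidecar)) stop("table carries no normalization attribute")
  jsonlite::write_json(sidecar, path, digits = NA, pretty = TRUE)
  invisible(path)
}
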