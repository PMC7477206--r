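#' Maximum-likelihood SEM engine
#'
#' Fits `sem_spec` models to data or to a covariance matrix by normal-theory
#' maximum likelihood, in RAM form: with `A` the matrix of directed edges
#' (loadings and paths) and `S` the symmetric matrix of (residual)
#' variances/covariances, the model-implied covariance of the observed
#' variables is `F (I-A)^-1 S (I-A)^-T F^T`. Missing data can be handled by
#' full-information maximum likelihood (casewise Gaussian likelihood on each
#' row's observed subset, with saturated means).
#'
#' @name sem_engine
NULL

# ---- RAM plumbing ---------------------------------------------------------

ram_matrices <- function(spec, theta, pt = sem_ptable(spec)) {
  t_all <- length(spec$observed) + length(spec$latents)
  if (sum(pt$free) != length(theta))
    stop("theta has length ", length(theta), ", expected ", sum(pt$free))
  val <- pt$value
  val[pt$free] <- theta
  A <- matrix(0, t_all, t_all)
  S <- matrix(0, t_all, t_all)
  isA <- pt$matrix == "A"
  A[cbind(pt$row[isA], pt$col[isA])] <- val[isA]
  S[cbind(pt$row[!isA], pt$col[!isA])] <- val[!isA]
  S[cbind(pt$col[!isA], pt$row[!isA])] <- val[!isA]
  list(A = A, S = S, obs = seq_along(spec$observed))
}

implied_moments <- function(spec, theta, pt = sem_ptable(spec)) {
  ram <- ram_matrices(spec, theta, pt)
  if (!all(is.finite(ram$A)) || !all(is.finite(ram$S)))
    stop("non-finite parameter values")
  t_all <- nrow(ram$A)
  B <- solve(diag(t_all) - ram$A)
  M <- B %*% ram$S %*% t(B)          # covariance of all (observed + latent)
  list(Sigma = M[ram$obs, ram$obs, drop = FALSE], Sigma_all = M, B = B,
       ram = ram)
}

#' Model-implied covariance matrix
#'
#' @param spec A [sem_spec()].
#' @param theta Free-parameter vector, ordered as in [sem_ptable()].
#' @return The implied covariance of the observed variables, with dimnames.
#' @export
implied_covariance <- function(spec, theta) {
  Sigma <- implied_moments(spec, theta)$Sigma
  dimnames(Sigma) <- list(spec$observed, spec$observed)
  Sigma
}

#' Maximum-likelihood discrepancy between sample and implied covariance
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, non-negative, zero iff
#' `S == Sigma`.
#'
#' @param S Sample covariance (positive definite).
#' @param Sigma Implied covariance (positive definite, same order).
#' @return Scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- ncol(S)
  if (ncol(Sigma) != p) stop("dimension mismatch")
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive definite"))
  cSig <- tryCatch(chol(Sigma),
                   error = function(e) stop("Sigma is not positive definite"))
  2 * sum(log(diag(cSig))) + sum(diag(chol2inv(cSig) %*% S)) -
    2 * sum(log(diag(cS))) - p
}

# derivative helper: for each free parameter return the rank-2 factors of
# dSigma (u w' + w u'), as index/selection into precomputed matrices
dsigma_factors <- function(pt) {
  fr <- pt[pt$free, , drop = FALSE]
  list(isA = fr$matrix == "A", row = fr$row, col = fr$col,
       type = fr$type, label = fr$label)
}

# gradient of sum(W * dSigma_k) for all free params, W symmetric p x p
ram_gradient <- function(W, mom, fac) {
  obs <- mom$ram$obs
  C <- mom$B[obs, , drop = FALSE]        # p x t ("F B")
  Mo <- mom$Sigma_all[, obs, drop = FALSE] # t x p ("(B S B')F'")
  WC <- W %*% C                           # p x t
  WMt <- W %*% t(Mo)                      # p x t
  g <- numeric(length(fac$row))
  for (k in seq_along(g)) {
    i <- fac$row[k]; j <- fac$col[k]
    if (fac$isA[k]) {
      # dSigma = C[,i] Mo[j,]' + Mo[j,] C[,i]'
      g[k] <- 2 * sum(C[, i] * WMt[, j])
    } else if (i == j) {
      g[k] <- sum(C[, i] * WC[, i])
    } else {
      g[k] <- 2 * sum(C[, i] * WC[, j])
    }
  }
  g
}

# ---- covariance ML --------------------------------------------------------

ml_objective <- function(theta, spec, pt, S, logdetS) {
  mom <- tryCatch(implied_moments(spec, theta, pt), error = function(e) NULL)
  if (is.null(mom)) return(list(value = 1e10 + sum(theta^2), mom = NULL))
  ch <- tryCatch(chol(mom$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10 + sum(theta^2), mom = mom))
  Sinv <- chol2inv(ch)
  value <- 2 * sum(log(diag(ch))) + sum(Sinv * S) - logdetS - ncol(S)
  list(value = value, mom = mom, Sigma_inv = Sinv)
}

ml_gradient <- function(theta, spec, pt, S, fac) {
  o <- ml_objective(theta, spec, pt, S, 0)
  if (is.null(o$Sigma_inv)) return(2 * theta)
  # dF = tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma]
  W <- o$Sigma_inv - o$Sigma_inv %*% S %*% o$Sigma_inv
  ram_gradient(W, o$mom, fac)
}

# ---- FIML -----------------------------------------------------------------

missing_patterns <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, paste, collapse = "")
  groups <- split(seq_len(nrow(X)), key)
  pats <- lapply(groups, function(rows) {
    o <- which(obs[rows[1L], ])
    Xo <- X[rows, o, drop = FALSE]
    ng <- length(rows)
    xbar <- colMeans(Xo)
    d <- sweep(Xo, 2L, xbar)
    list(obs = o, n = ng, xbar = xbar, scatter = crossprod(d))
  })
  list(patterns = pats, n = nrow(X))
}

# objective: -2 * loglik (including 2*pi constants)
fiml_objective <- function(theta_full, spec, pt, pats, n_free, p) {
  theta <- theta_full[seq_len(n_free)]
  mu <- theta_full[-seq_len(n_free)]
  mom <- tryCatch(implied_moments(spec, theta, pt), error = function(e) NULL)
  if (is.null(mom)) return(list(value = 1e10 + sum(theta_full^2)))
  Sigma <- mom$Sigma
  val <- 0
  info <- vector("list", length(pats))
  for (g in seq_along(pats)) {
    pg <- pats[[g]]
    So <- Sigma[pg$obs, pg$obs, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10 + sum(theta_full^2)))
    Oinv <- chol2inv(ch)
    d <- pg$xbar - mu[pg$obs]
    val <- val + pg$n * (2 * sum(log(diag(ch))) +
                         length(pg$obs) * log(2 * pi)) +
      sum(Oinv * pg$scatter) + pg$n * drop(t(d) %*% Oinv %*% d)
    info[[g]] <- list(Oinv = Oinv, d = d)
  }
  list(value = val, mom = mom, info = info)
}

fiml_gradient <- function(theta_full, spec, pt, pats, n_free, p, fac) {
  o <- fiml_objective(theta_full, spec, pt, pats, n_free, p)
  if (is.null(o$mom)) return(2 * theta_full)
  W <- matrix(0, p, p)
  gmu <- numeric(p)
  for (g in seq_along(pats)) {
    pg <- pats[[g]]
    Oinv <- o$info[[g]]$Oinv
    d <- o$info[[g]]$d
    Oid <- Oinv %*% d
    # d/dSigma_o of the pattern's -2 loglik
    Wg <- pg$n * Oinv - Oinv %*% pg$scatter %*% Oinv -
      pg$n * (Oid %*% t(Oid))
    W[pg$obs, pg$obs] <- W[pg$obs, pg$obs] + Wg
    gmu[pg$obs] <- gmu[pg$obs] - 2 * pg$n * Oid
  }
  c(ram_gradient(W, o$mom, fac), gmu)
}

# EM for the unrestricted (saturated) Gaussian model under missingness;
# returns MLE mean/covariance (divisor n) and the maximised loglik
em_saturated <- function(X, max_iter = 500, tol = 1e-8) {
  p <- ncol(X)
  mp <- missing_patterns(X)
  pats <- mp$patterns
  n <- mp$n
  mu <- vapply(seq_len(p), function(j) mean(X[, j], na.rm = TRUE), numeric(1))
  v <- vapply(seq_len(p), function(j) stats::var(X[, j], na.rm = TRUE) *
                (sum(!is.na(X[, j])) - 1) / sum(!is.na(X[, j])), numeric(1))
  Sigma <- diag(pmax(v, 1e-8), p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (pg in pats) {
      o <- pg$obs; m <- setdiff(seq_len(p), o)
      So <- Sigma[o, o, drop = FALSE]
      ch <- chol(So)
      Oinv <- chol2inv(ch)
      d <- pg$xbar - mu[o]
      ll <- ll - 0.5 * (pg$n * (2 * sum(log(diag(ch))) +
                                length(o) * log(2 * pi)) +
                        sum(Oinv * pg$scatter) +
                        pg$n * drop(t(d) %*% Oinv %*% d))
      # pattern-level expected sufficient statistics
      Exo <- pg$xbar
      Sxx_o <- pg$scatter + pg$n * (pg$xbar %*% t(pg$xbar)) # sum of x x'
      sum_x[o] <- sum_x[o] + pg$n * Exo
      sum_xx[o, o] <- sum_xx[o, o] + Sxx_o
      if (length(m)) {
        Amat <- Sigma[m, o, drop = FALSE] %*% Oinv
        mu_m <- mu[m] + drop(Amat %*% d)               # mean of imputations
        # sum_i xhat_m,i = n*mu[m] + A (sum_i x_o,i - n mu_o)
        sum_xm <- pg$n * mu[m] + Amat %*% (pg$n * d)
        sum_x[m] <- sum_x[m] + drop(sum_xm)
        Cmm <- Sigma[m, m, drop = FALSE] -
          Amat %*% t(Sigma[m, o, drop = FALSE])
        Sxo_c <- pg$scatter                              # centred scatter
        sum_mo <- pg$n * (mu_m %*% t(pg$xbar)) + Amat %*% Sxo_c
        sum_xx[m, o] <- sum_xx[m, o] + sum_mo
        sum_xx[o, m] <- sum_xx[o, m] + t(sum_mo)
        sum_mm <- pg$n * (mu_m %*% t(mu_m)) +
          Amat %*% Sxo_c %*% t(Amat) + pg$n * Cmm
        sum_xx[m, m] <- sum_xx[m, m] + sum_mm
      }
    }
    mu_new <- sum_x / n
    Sigma_new <- sum_xx / n - mu_new %*% t(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    mu <- mu_new; Sigma <- Sigma_new
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it)
}

# ---- fitting --------------------------------------------------------------

start_values <- function(spec, pt, S) {
  vars <- c(spec$observed, names(spec$latents))
  diagS <- stats::setNames(diag(S), spec$observed)
  marker <- vapply(spec$latents, `[`, character(1), 1L)
  th <- numeric(sum(pt$free))
  fr <- pt[pt$free, , drop = FALSE]
  for (k in seq_len(nrow(fr))) {
    type <- fr$type[k]
    v_row <- vars[fr$row[k]]; v_col <- vars[fr$col[k]]
    th[k] <- if (type == "loading") {
      m <- marker[[v_col]]
      if (v_row %in% spec$observed && m %in% spec$observed)
        S[match(v_row, spec$observed), match(m, spec$observed)] /
          max(S[match(m, spec$observed), match(m, spec$observed)], 1e-8)
      else 1
    } else if (type == "path") 0
    else if (type == "variance") {
      if (v_row %in% spec$observed) {
        lat_of <- names(spec$latents)[vapply(spec$latents, function(x)
          v_row %in% x, logical(1))]
        if (length(lat_of)) 0.5 * diagS[[v_row]] else diagS[[v_row]]
      } else {
        m <- marker[[v_row]]
        0.4 * diagS[[m]]
      }
    } else { # covariance: sample value for exogenous observed pairs, else 0
      is_indicator <- function(v) any(vapply(spec$latents, function(x)
        v %in% x, logical(1)))
      if (v_row %in% spec$observed && v_col %in% spec$observed &&
          !is_indicator(v_row) && !is_indicator(v_col))
        S[match(v_row, spec$observed), match(v_col, spec$observed)]
      else 0
    }
  }
  names(th) <- fr$label
  th
}

param_bounds <- function(pt, variance_floor = 1e-6) {
  fr <- pt[pt$free, , drop = FALSE]
  lower <- ifelse(fr$type == "variance", variance_floor, -Inf)
  lower
}

#' Fit a structural equation model
#'
#' Normal-theory maximum likelihood on the sample covariance (listwise
#' complete data), or full-information maximum likelihood (`estimator =
#' "FIML"`) using every observation's observed variable subset with
#' saturated means. Optimisation is quasi-Newton (`nlminb`) on the free
#' parameters with analytic gradients; non-converged fits are restarted from
#' deterministically perturbed start values. Residual variances are bounded
#' below at `variance_floor`, with a warning when an estimate lands on the
#' bound (Heywood case).
#'
#' @param spec A [sem_spec()] with `identification = "marker"`.
#' @param data Data frame or matrix containing the spec's observed columns.
#'   Alternatively supply `sample_cov` and `n`.
#' @param sample_cov Sample covariance matrix (used when `data` is NULL;
#'   unbiased, divisor n-1).
#' @param n Sample size accompanying `sample_cov`.
#' @param estimator `"ML"` (covariance-based, listwise) or `"FIML"`.
#' @param likelihood For ML: `"wishart"` uses the unbiased sample covariance
#'   and the `(n-1)` chi-square multiplier; `"normal"` uses the divisor-n
#'   covariance and multiplier `n`, matching the FIML objective exactly on
#'   complete data.
#' @param se Compute standard errors from the (finite-difference of the
#'   analytic gradient) Hessian. Disable for speed in simulations.
#' @param start Optional named start vector (free parameters in
#'   [sem_ptable()] order).
#' @param max_restarts Restarts with perturbed starts on non-convergence.
#' @param variance_floor Lower bound for variance parameters.
#' @param gradient_tol Relative gradient-norm threshold declaring
#'   convergence.
#' @return An object of class `sem_fit`: parameter table with estimates,
#'   standardised solution, log-likelihood, chi-square and df, baseline
#'   model, fit indices (CFI/TLI/RMSEA), convergence diagnostics.
#' @export
fit_sem <- function(spec, data = NULL, sample_cov = NULL, n = NULL,
                    estimator = c("ML", "FIML"),
                    likelihood = c("wishart", "normal"),
                    se = TRUE, start = NULL, max_restarts = 3L,
                    variance_floor = 1e-6, gradient_tol = 1e-5) {
  estimator <- match.arg(estimator)
  likelihood <- match.arg(likelihood)
  pt <- sem_ptable(spec)
  fac <- dsigma_factors(pt)
  p <- length(spec$observed)

  if (estimator == "ML") {
    if (!is.null(data)) {
      X <- as.matrix(as.data.frame(data)[, spec$observed, drop = FALSE])
      X <- X[stats::complete.cases(X), , drop = FALSE]
      n <- nrow(X)
      if (n <= p) stop("too few complete cases (", n, ") for ", p,
                       " variables")
      S <- stats::cov(X)
    } else {
      if (is.null(sample_cov) || is.null(n))
        stop("supply either data or sample_cov + n")
      S <- as.matrix(sample_cov)
      if (!is.null(dimnames(S)[[1]])) {
        if (!all(spec$observed %in% rownames(S)))
          stop("sample_cov lacks observed variables")
        S <- S[spec$observed, spec$observed]
      }
    }
    mult <- if (likelihood == "wishart") n - 1 else n
    if (likelihood == "normal") S <- S * (n - 1) / n
    logdetS <- 2 * sum(log(diag(chol(S))))

    obj <- function(th) ml_objective(th, spec, pt, S, logdetS)$value
    grd <- function(th) ml_gradient(th, spec, pt, S, fac)
    th0 <- if (is.null(start)) start_values(spec, pt, S) else start
  } else {
    if (is.null(data)) stop("FIML requires raw data")
    X <- as.matrix(as.data.frame(data)[, spec$observed, drop = FALSE])
    mp <- missing_patterns(X)
    pats <- mp$patterns
    n <- mp$n
    # start from listwise ML when enough complete rows, else diagonal starts
    Xc <- X[stats::complete.cases(X), , drop = FALSE]
    S_start <- if (nrow(Xc) > p + 1) stats::cov(Xc) else {
      d <- vapply(seq_len(p), function(j) stats::var(X[, j], na.rm = TRUE),
                  numeric(1))
      diag(d, p)
    }
    nfree <- sum(pt$free)
    th_model <- if (is.null(start)) start_values(spec, pt, S_start) else start
    mu0 <- vapply(seq_len(p), function(j) mean(X[, j], na.rm = TRUE),
                  numeric(1))
    th0 <- c(th_model, mu0)
    # optimise the per-observation deviance so tolerances are scale-free
    obj <- function(th) fiml_objective(th, spec, pt, pats, nfree, p)$value / n
    grd <- function(th) fiml_gradient(th, spec, pt, pats, nfree, p, fac) / n
  }

  lower <- param_bounds(pt, variance_floor)
  if (estimator == "FIML") lower <- c(lower, rep(-Inf, p))

  best <- NULL
  restarts <- 0L
  for (attempt in 0:max_restarts) {
    th_try <- if (attempt == 0) th0 else
      th0 * (1 + 0.15 * sin(seq_along(th0) * attempt)) +
        0.05 * attempt * cos(seq_along(th0))
    th_try <- pmax(th_try, lower + 1e-8)
    opt <- tryCatch(
      stats::nlminb(th_try, obj, gradient = grd, lower = lower,
                    control = list(iter.max = 1000, eval.max = 2000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) { restarts <- restarts + 1L; next }
    g <- grd(opt$par)
    gnorm <- max(abs(g)) / max(1, abs(opt$objective))
    ok <- is.finite(opt$objective) && opt$objective < 1e9 &&
      gnorm < gradient_tol
    if (is.null(best) || opt$objective < best$objective - 1e-10)
      best <- c(opt, list(gnorm = gnorm, ok = ok))
    if (ok && attempt == 0) break
    if (!is.null(best) && best$ok) break
    restarts <- restarts + 1L
  }
  if (is.null(best))
    stop("fit_sem: optimisation failed after ", restarts, " restarts")

  # Newton polish from the quasi-Newton solution: tightens the gradient norm
  # to near machine precision when no bound is active
  par <- best$par
  if (all(par > lower + 1e-7)) {
    f_cur <- obj(par)
    for (it in 1:5) {
      g <- grd(par)
      if (max(abs(g)) < 1e-10) break
      H <- gradient_hessian(grd, par)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- par - step
      if (any(cand <= lower)) break
      f_new <- obj(cand)
      if (!is.finite(f_new) || f_new > f_cur + 1e-10) break
      par <- cand; f_cur <- f_new
    }
    g <- grd(par)
    best$par <- par
    best$objective <- f_cur
    best$gnorm <- max(abs(g)) / max(1, abs(f_cur))
    best$ok <- best$ok || best$gnorm < gradient_tol
  }
  converged <- isTRUE(best$ok)
  if (!converged)
    warning("fit_sem: gradient norm ", signif(best$gnorm, 3),
            " above tolerance after ", restarts, " restarts")

  theta_full <- best$par
  nfree <- sum(pt$free)
  theta <- theta_full[seq_len(nfree)]
  names(theta) <- pt$label[pt$free]

  # Heywood check
  var_idx <- which(pt$type[pt$free] == "variance")
  if (any(theta[var_idx] <= variance_floor * (1 + 1e-6)))
    warning("Heywood case: variance estimate(s) at the lower bound: ",
            paste(names(theta)[var_idx][theta[var_idx] <=
              variance_floor * (1 + 1e-6)], collapse = ", "))

  df <- model_df(spec, p)

  if (estimator == "ML") {
    Fmin <- best$objective
    chisq <- max(mult * Fmin, 0)
    loglik <- -0.5 * mult * (Fmin + logdetS + p) - 0.5 * n * p * log(2 * pi)
    # baseline/independence model: diagonal implied covariance
    F0 <- sum(log(diag(S))) - logdetS
    chisq0 <- max(mult * F0, 0)
    df0 <- p * (p - 1) / 2
    mu_hat <- NULL
  } else {
    loglik <- -0.5 * best$objective * n
    sat <- em_saturated(X)
    chisq <- max(2 * (sat$loglik - loglik), 0)
    # independence baseline: per-variable univariate Gaussian MLE
    ll0 <- 0
    for (j in seq_len(p)) {
      xj <- X[, j]; xj <- xj[!is.na(xj)]
      s2 <- mean((xj - mean(xj))^2)
      ll0 <- ll0 - 0.5 * length(xj) * (log(2 * pi) + log(s2) + 1)
    }
    chisq0 <- max(2 * (sat$loglik - ll0), 0)
    df0 <- p * (p - 1) / 2
    mu_hat <- stats::setNames(theta_full[-seq_len(nfree)], spec$observed)
  }

  indices <- fit_indices(chisq, df, chisq0, df0, n)

  est <- pt$value
  est[pt$free] <- theta
  pt$est <- est

  se_vec <- rep(NA_real_, length(theta_full))
  if (se) {
    H <- gradient_hessian(grd, theta_full)
    scale_fac <- if (estimator == "ML") 2 / mult else 2 / n
    acov <- tryCatch(scale_fac * solve(H), error = function(e) NULL)
    if (!is.null(acov)) {
      dg <- diag(acov)
      se_vec <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  pt$se <- NA_real_
  pt$se[pt$free] <- se_vec[seq_len(nfree)]

  fit <- list(spec = spec, ptable = pt, theta = theta,
              mu = if (estimator == "FIML") mu_hat else NULL,
              loglik = loglik, chisq = chisq, df = df,
              baseline = c(chisq = chisq0, df = df0),
              fit = indices, n_used = n, estimator = estimator,
              likelihood = if (estimator == "ML") likelihood else "normal",
              converged = converged, gradient_norm = best$gnorm,
              restarts = restarts, objective = best$objective)
  class(fit) <- "sem_fit"
  fit$standardized <- standardize_solution(fit)
  fit
}

# Hessian by central finite differences of an analytic gradient
gradient_hessian <- function(grd, theta, h_rel = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (grd(tp) - grd(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Incremental and absolute fit indices
#'
#' `CFI = 1 - max(chisq - df, 0) / max(chisq0 - df0, chisq - df, 0)`;
#' `TLI = (chisq0/df0 - chisq/df) / (chisq0/df0 - 1)`;
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n-1)))`. CFI and TLI are clipped
#' to [0, 1] for reporting; RMSEA is `NA` for a saturated model (df = 0).
#'
#' @param chisq,df Model test statistic and degrees of freedom.
#' @param null_chisq,null_df Baseline (independence) model statistic and df.
#' @param n Sample size.
#' @return Named vector `c(CFI, TLI, RMSEA)`.
#' @export
fit_indices <- function(chisq, df, null_chisq, null_df, n) {
  d_m <- max(chisq - df, 0)
  d_0 <- max(null_chisq - null_df, d_m, 0)
  cfi <- if (d_0 > 0) 1 - d_m / d_0 else 1
  tli <- if (null_df > 0 && df > 0 && null_chisq / null_df != 1)
    (null_chisq / null_df - chisq / df) / (null_chisq / null_df - 1)
  else NA_real_
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else NA_real_
  c(CFI = min(max(cfi, 0), 1),
    TLI = if (is.na(tli)) NA_real_ else min(max(tli, 0), 1),
    RMSEA = rmsea)
}

#' Standardised solution
#'
#' Every directed edge is rescaled by the implied SD of its source over the
#' implied SD of its target; covariances become correlations; variances
#' become proportions of the variable's implied variance. Invariant to the
#' identification convention and to affine rescaling of indicators.
#'
#' @param fit A [fit_sem()] result, or a list with `spec` and `theta`.
#' @return The parameter table with a `std` column.
#' @export
standardize_solution <- function(fit) {
  spec <- fit$spec
  pt <- if (!is.null(fit$ptable)) fit$ptable else sem_ptable(spec)
  if (is.null(pt$est)) {
    est <- pt$value
    est[pt$free] <- fit$theta
    pt$est <- est
  }
  mom <- implied_moments(spec, fit$theta, sem_ptable(spec))
  sdv <- sqrt(diag(mom$Sigma_all))
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("standardize_solution: zero or negative implied variance")
  pt$std <- NA_real_
  isA <- pt$matrix == "A"
  pt$std[isA] <- pt$est[isA] * sdv[pt$col[isA]] / sdv[pt$row[isA]]
  isS <- !isA
  pt$std[isS] <- pt$est[isS] / (sdv[pt$row[isS]] * sdv[pt$col[isS]])
  pt[, c("label", "type", "free", "est", "se", "std")[
    c("label", "type", "free", "est", "se", "std") %in% names(pt)]]
}

#' Chi-square difference test between nested models
#'
#' @param full Fit of the less constrained model.
#' @param nested Fit of the constrained model (free parameters a subset of
#'   the full model's).
#' @return List with `delta_chisq`, `delta_df`, `p_value`.
#' @export
chi_square_difference <- function(full, nested) {
  if (!inherits(full, "sem_fit") || !inherits(nested, "sem_fit"))
    stop("both arguments must be sem_fit objects")
  full_free <- full$ptable$label[full$ptable$free]
  nested_free <- nested$ptable$label[nested$ptable$free]
  if (!all(nested_free %in% full_free))
    stop("models are not nested: constrained model frees parameters absent ",
         "from the full model")
  delta_df <- nested$df - full$df
  if (delta_df < 0) stop("models are not nested: nested model has lower df")
  delta_chisq <- nested$chisq - full$chisq
  if (delta_chisq < -1e-8)
    warning("negative chi-square difference (", signif(delta_chisq, 3),
            "); the 'nested' model fits better than the full model")
  delta_chisq <- max(delta_chisq, 0)
  p <- if (delta_df == 0) 1 else
    stats::pchisq(delta_chisq, delta_df, lower.tail = FALSE)
  list(delta_chisq = delta_chisq, delta_df = delta_df, p_value = p)
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("sem_fit (", x$estimator, "): n =", x$n_used,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  cat(sprintf("  chisq = %.3f, df = %d, CFI = %.3f, TLI = %.3f, RMSEA = %.4f\n",
              x$chisq, x$df, x$fit[["CFI"]], x$fit[["TLI"]],
              x$fit[["RMSEA"]]))
  std <- x$standardized
  print(utils::head(std[std$free, ], 40), digits = digits)
  invisible(x)
}

#' Export a fitted model
#'
#' Writes estimates, standard errors, the standardised solution and fit
#' indices as JSON, plus a flat TSV parameter table.
#'
#' @param fit A [fit_sem()] result.
#' @param json_path,tsv_path Output paths (either may be NULL).
#' @return Invisibly, the list that was serialised.
#' @export
write_sem_fit <- function(fit, json_path = NULL, tsv_path = NULL) {
  std <- fit$standardized
  out <- list(
    estimator = fit$estimator, n_used = fit$n_used,
    loglik = fit$loglik, chisq = fit$chisq, df = fit$df,
    baseline = as.list(fit$baseline), fit_indices = as.list(fit$fit),
    converged = fit$converged, gradient_norm = fit$gradient_norm,
    parameters = std
  )
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, digits = NA, pretty = TRUE,
                         auto_unbox = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(std, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(out)
}
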