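#' Synthetic ageing-cohort generator
#'
#' Generates UK-Biobank-like cohorts with a known latent structural ground
#' truth, so that every stage of the analysis chain (risk scoring,
#' preprocessing, SEM, window curves, mediation) can be validated against
#' injected parameters. Marginals are calibrated to the published population
#' characteristics: age 44-73 with mean 62 and SD 7; APOE genotype mix
#' 76/19/1/4% (e3/3, single e4, e4/4, other); 5% diabetic, 21% on
#' cholesterol medication, 22% on antihypertensives, 78% never-smokers.
#' Structural coefficients default to the published standardised path
#' values.
#'
#' @name synthetic_cohort
NULL

#' Generator parameters
#'
#' All knobs of [generate_cohort()] with their calibrated defaults. The
#' structural block holds standardised coefficients of the ground-truth
#' model; the loading block holds standardised indicator loadings. The
#' cerebrovascular risk score is not drawn directly: raw risk-factor fields
#' are generated with age-dependent prevalences and the score is computed by
#' [score_cohort()], so the scoring rules sit inside the generative loop.
#'
#' @param n Cohort size.
#' @param preset `"default"` (n = 22,059), `"recovery"` (n = 20,000) or
#'   `"tiny"` (n = 200); overridden by an explicit `n`.
#' @param missing_rate Cell-level missingness rate for
#'   [inject_missingness()] (0 = complete data).
#' @param structural Named standardised coefficients of the ground-truth
#'   path model.
#' @param loadings Standardised indicator loadings per latent.
#' @return Named list of generator parameters.
#' @export
cohort_params <- function(n = NULL,
                          preset = c("default", "recovery", "tiny"),
                          missing_rate = 0,
                          structural = NULL, loadings = NULL) {
  preset <- match.arg(preset)
  if (is.null(n)) n <- c(default = 22059, recovery = 20000, tiny = 200)[[preset]]
  p <- list(
    n = n,
    age = list(mean = 62, sd = 7, range = c(44, 73)),
    genotype_probs = c("e3/e3" = 0.76, "e3/e4" = 0.19, "e4/e4" = 0.01,
                       "e2/e3" = 0.035, "e2/e2" = 0.005),
    prevalence = c(diabetes = 0.05, chol_med = 0.21, bp_med = 0.22,
                   non_smoker = 0.78),
    # logistic age slopes (per SD of age) of the risk-factor prevalences;
    # intercepts are solved at generation time so marginals hit the targets
    age_slopes = c(diabetes = 0.3, chol_med = 0.35, bp_med = 0.35,
                   ever_smoker = 0.1, current_smoker = -0.3),
    structural = c(age_wmh = 0.35, cvr_wmh = 0.13,
                   age_gm = -0.45, cvr_gm = -0.07, wmh_gm = -0.10,
                   age_wm = -0.35, cvr_wm = -0.01, wmh_wm = -0.15,
                   gm_ef = 0.32, wm_ef = 0.34, age_cvr = 0.25),
    loadings = list(gm = c(ag = 0.7, prc = 0.7, cg = 0.7, sfg = 0.7,
                           fp = 0.7, mtg = 0.7),
                    wm = c(icvf = 0.8, od = 0.8),
                    ef = c(rt = 0.49, pairs = 0.25)),
    resid_cov = c("ag~~prc" = 0.15, "sfg~~fp" = 0.15),
    sbp = list(mean = 138, sd = 18, age_loading = 0.35, reading_sd = 4),
    dbp = list(mean = 82, sd = 10, sbp_loading = 0.55),
    sbp_link = list(unmedicated = 0.12, medicated = 0.12, plateau = 140,
                    med_scale = 15),
    rt = list(mean = 540, sd = 110, floor = 180, trials = 12,
              sdlog = 0.25, outlier_frac = 0.02),
    pairs = list(mu = 4, size = 3),
    wmh = list(croot_mean = 16, croot_sd = 4),
    volumes = list(mean = c(ag = 11500, prc = 14200, cg = 9800, sfg = 21000,
                            fp = 28000, mtg = 16500),
                   sd = c(ag = 1400, prc = 1600, cg = 1200, sfg = 2400,
                          fp = 3000, mtg = 1900)),
    noddi = list(icvf_mean = 0.55, icvf_sd = 0.035,
                 od_mean = 0.45, od_sd = 0.04),
    townsend = list(mean = -1.3, sd = 2.9, cvr_loading = 0.12),
    missing_rate = missing_rate
  )
  if (!is.null(structural)) p$structural[names(structural)] <- structural
  if (!is.null(loadings)) p$loadings[names(loadings)] <- loadings
  stopifnot(abs(sum(p$genotype_probs) - 1) < 1e-8,
            all(p$genotype_probs >= 0),
            all(abs(p$structural) < 1))
  p
}

# pre-truncation parameters such that the truncated normal on `range`
# has the target mean and sd
calibrate_truncnorm <- function(mean, sd, range) {
  moments <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    a <- (range[1] - mu) / sig; b <- (range[2] - mu) / sig
    Z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sig * (da - db) / Z
    v <- sig^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    c(m, sqrt(v))
  }
  obj <- function(par) sum((moments(par) - c(mean, sd))^2)
  opt <- stats::optim(c(mean, log(sd * 1.2)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = opt$par[1], sigma = exp(opt$par[2]))
}

# intercept a with mean(plogis(a + eta)) = target
calibrate_intercept <- function(target, eta) {
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target,
                 c(-25, 25), tol = 1e-12)$root
}

# covariance among the structural variables (all unit variance) implied by
# the standardised coefficients; returns the matrix and residual variances
structural_covariance <- function(st) {
  svars <- c("age", "cvr", "wmh", "gm", "wm", "ef")
  parents <- list(wmh = c(age = "age_wmh", cvr = "cvr_wmh"),
                  gm = c(age = "age_gm", cvr = "cvr_gm", wmh = "wmh_gm"),
                  wm = c(age = "age_wm", cvr = "cvr_wm", wmh = "wmh_wm"),
                  ef = c(gm = "gm_ef", wm = "wm_ef"))
  Sc <- diag(6); dimnames(Sc) <- list(svars, svars)
  Sc["age", "cvr"] <- Sc["cvr", "age"] <- st[["age_cvr"]]
  psi <- c(age = 1, cvr = 1)
  for (v in names(parents)) {
    pa <- names(parents[[v]])
    b <- st[parents[[v]]]
    done <- svars[seq_len(match(v, svars) - 1L)]
    cv <- drop(Sc[done, pa, drop = FALSE] %*% b)
    varexp <- drop(t(b) %*% Sc[pa, pa] %*% b)
    psi[v] <- 1 - varexp
    if (psi[v] <= 0)
      stop("structural coefficients imply non-positive residual variance ",
           "for '", v, "'")
    Sc[done, v] <- Sc[v, done] <- cv
    Sc[v, v] <- 1
  }
  list(Sigma = Sc, psi = psi)
}

#' Ground-truth model and parameter vector
#'
#' The exact specification and free-parameter vector used by
#' [generate_cohort()], on the standardised scale (every structural variable
#' and indicator has unit variance; identification `"none"`, all loadings
#' free). `implied_covariance(spec, theta)` is validated to be positive
#' definite.
#'
#' @param params [cohort_params()].
#' @return List with `spec` (a [sem_spec()]), `theta` (named), and the
#'   structural covariance `Sigma_structural`.
#' @export
ground_truth <- function(params = cohort_params()) {
  st <- params$structural
  sc <- structural_covariance(st)
  spec <- fp_sem_spec(identification = "none")
  pt <- sem_ptable(spec)
  lab <- pt$label[pt$free]
  val <- stats::setNames(rep(NA_real_, length(lab)), lab)

  lam <- params$loadings
  for (L in names(lam)) for (ind in names(lam[[L]]))
    val[paste0(L, "=~", ind)] <- lam[[L]][[ind]]

  path_label <- c(age_wmh = "wmh~age", cvr_wmh = "wmh~cvr",
                  age_gm = "gm~age", cvr_gm = "gm~cvr", wmh_gm = "gm~wmh",
                  age_wm = "wm~age", cvr_wm = "wm~cvr", wmh_wm = "wm~wmh",
                  gm_ef = "ef~gm", wm_ef = "ef~wm")
  for (nm in names(path_label)) val[path_label[[nm]]] <- st[[nm]]

  val["age~~age"] <- 1
  val["cvr~~cvr"] <- 1
  val["wmh~~wmh"] <- sc$psi[["wmh"]]
  for (L in names(lam)) {
    val[paste0(L, "~~", L)] <- sc$psi[[L]]
    for (ind in names(lam[[L]]))
      val[paste0(ind, "~~", ind)] <- 1 - lam[[L]][[ind]]^2
  }
  val["age~~cvr"] <- st[["age_cvr"]]
  for (nm in names(params$resid_cov)) val[nm] <- params$resid_cov[[nm]]

  if (anyNA(val))
    stop("internal: unassigned ground-truth parameters: ",
         paste(names(val)[is.na(val)], collapse = ", "))
  Sigma <- implied_covariance(spec, unname(val))
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("ground-truth implied covariance is not positive definite ",
         "(min eigenvalue ", signif(ev, 3), "); check structural/loading/",
         "residual-covariance blocks")
  list(spec = spec, theta = val, Sigma_structural = sc$Sigma,
       psi = sc$psi)
}

cohort_column_dictionary <- function(params = cohort_params()) {
  c("id", "age_at_scan", "sex", "townsend",
    "sbp_1", "sbp_2", "dbp_1", "dbp_2",
    "on_bp_medication", "on_cholesterol_medication", "diabetic",
    "waist_cm", "hip_cm",
    "smoking_status", "cigarettes_per_day", "age_started_smoking",
    "age_stopped_smoking",
    "apoe_genotype",
    "wmh_mm3", "vol_ag", "vol_prc", "vol_cg", "vol_sfg", "vol_fp",
    "vol_mtg", "slf_icvf", "slf_od",
    paste0("rt_trial_", sprintf("%02d", seq_len(params$rt$trials))),
    "pairs_errors")
}

#' Generate a synthetic cohort
#'
#' Draws raw participant-level fields (demographics, two blood-pressure
#' readings, medication and diagnosis flags, smoking history, waist/hip,
#' APOE genotype, WMH volume, six frontoparietal grey-matter volumes, SLF
#' NODDI indicators, 12 reaction-time trials including a small fraction of
#' out-of-window responses, pairs-matching errors) consistent with the
#' ground-truth structural model of [ground_truth()]. The cerebrovascular
#' risk score used in the structural equations is the rule-based score
#' computed from the generated raw fields, standardised within the cohort.
#'
#' @param params [cohort_params()].
#' @param seed Mandatory RNG seed; identical `(params, seed)` give an
#'   identical table.
#' @return Data frame (one participant per row) with attributes `params`
#'   and `seed`.
#' @export
generate_cohort <- function(params = cohort_params(), seed) {
  if (missing(seed)) stop("generate_cohort: a seed is required")
  n <- params$n
  if (n == 0) {
    cols <- cohort_column_dictionary(params)
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
    attr(out, "params") <- params; attr(out, "seed") <- seed
    return(out)
  }
  set.seed(seed)
  st <- params$structural
  sc <- structural_covariance(st)

  # -- demographics ---------------------------------------------------------
  tn <- calibrate_truncnorm(params$age$mean, params$age$sd, params$age$range)
  plo <- stats::pnorm(params$age$range[1], tn$mu, tn$sigma)
  phi <- stats::pnorm(params$age$range[2], tn$mu, tn$sigma)
  age <- stats::qnorm(plo + stats::runif(n) * (phi - plo), tn$mu, tn$sigma)
  z_age <- as.vector(scale(age))
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")

  # -- blood pressure -------------------------------------------------------
  al <- params$sbp$age_loading
  sbp_core <- al * z_age + sqrt(1 - al^2) * stats::rnorm(n)
  sbp_true <- params$sbp$mean + params$sbp$sd * sbp_core
  dl <- params$dbp$sbp_loading
  dbp_core <- dl * sbp_core + sqrt(1 - dl^2) * stats::rnorm(n)
  dbp_true <- params$dbp$mean + params$dbp$sd * dbp_core
  rsd <- params$sbp$reading_sd
  sbp_1 <- sbp_true + stats::rnorm(n, 0, rsd)
  sbp_2 <- sbp_true + stats::rnorm(n, 0, rsd)
  dbp_1 <- dbp_true + stats::rnorm(n, 0, rsd)
  dbp_2 <- dbp_true + stats::rnorm(n, 0, rsd)

  # -- medication / diagnoses (marginals solved to the target prevalences) --
  sl <- params$age_slopes
  pv <- params$prevalence
  draw_flag <- function(target, eta) {
    a <- calibrate_intercept(target, eta)
    stats::runif(n) < stats::plogis(a + eta)
  }
  bp_med <- draw_flag(pv[["bp_med"]], sl[["bp_med"]] * z_age +
                        0.9 * sbp_core)
  chol_med <- draw_flag(pv[["chol_med"]], sl[["chol_med"]] * z_age)
  diabetic <- draw_flag(pv[["diabetes"]], sl[["diabetes"]] * z_age)

  # -- smoking --------------------------------------------------------------
  ever <- draw_flag(1 - pv[["non_smoker"]], sl[["ever_smoker"]] * z_age)
  n_ever <- sum(ever)
  current <- rep(FALSE, n)
  if (n_ever) {
    eta_c <- sl[["current_smoker"]] * z_age[ever]
    a_c <- calibrate_intercept(0.30, eta_c)
    current[ever] <- stats::runif(n_ever) < stats::plogis(a_c + eta_c)
  }
  status <- ifelse(!ever, "never", ifelse(current, "current", "ex"))
  cigs <- rep(NA_real_, n)
  started <- rep(NA_real_, n)
  stopped <- rep(NA_real_, n)
  if (n_ever) {
    cigs[ever] <- pmin(pmax(round(stats::rlnorm(n_ever, log(15), 0.55)), 1),
                       60)
    started[ever] <- pmin(pmax(round(stats::rnorm(n_ever, 17, 2)), 12), 25)
    is_ex <- ever & !current
    dur_frac <- stats::rbeta(sum(is_ex), 2, 2)
    stopped[is_ex] <- pmax(round(started[is_ex] +
      dur_frac * (age[is_ex] - started[is_ex])), started[is_ex])
  }

  # -- body composition -----------------------------------------------------
  hip <- pmax(stats::rnorm(n, 103, 9), 70)
  ratio0 <- ifelse(sex == "male", 0.93, 0.815)
  ratio_sd <- ifelse(sex == "male", 0.06, 0.07)
  ratio <- ratio0 + 0.008 * z_age + stats::rnorm(n, 0, ratio_sd)
  waist <- pmax(ratio, 0.5) * hip

  # -- genotype -------------------------------------------------------------
  geno <- sample(names(params$genotype_probs), n, replace = TRUE,
                 prob = params$genotype_probs)

  cohort <- data.frame(
    id = seq_len(n), age_at_scan = age, sex = sex,
    townsend = NA_real_,
    sbp_1 = sbp_1, sbp_2 = sbp_2, dbp_1 = dbp_1, dbp_2 = dbp_2,
    on_bp_medication = bp_med, on_cholesterol_medication = chol_med,
    diabetic = diabetic,
    waist_cm = waist, hip_cm = hip,
    smoking_status = status, cigarettes_per_day = cigs,
    age_started_smoking = started, age_stopped_smoking = stopped,
    apoe_genotype = geno,
    stringsAsFactors = FALSE
  )

  # -- rule-based CVR score inside the generative loop ----------------------
  cvr_total <- score_cohort(cohort)$total
  z_cvr <- as.vector(scale(cvr_total))

  tw <- params$townsend
  cohort$townsend <- tw$mean + tw$sd *
    (tw$cvr_loading * z_cvr + sqrt(1 - tw$cvr_loading^2) * stats::rnorm(n))

  # -- structural latents (standardised scale) ------------------------------
  z_wmh <- st[["age_wmh"]] * z_age + st[["cvr_wmh"]] * z_cvr +
    sqrt(sc$psi[["wmh"]]) * stats::rnorm(n)
  gm <- st[["age_gm"]] * z_age + st[["cvr_gm"]] * z_cvr +
    st[["wmh_gm"]] * z_wmh + sqrt(sc$psi[["gm"]]) * stats::rnorm(n)
  wm <- st[["age_wm"]] * z_age + st[["cvr_wm"]] * z_cvr +
    st[["wmh_wm"]] * z_wmh + sqrt(sc$psi[["wm"]]) * stats::rnorm(n)

  # blood-pressure link into the executive-function residual: linear decline
  # for the unmedicated, plateau below `plateau` mmHg for the medicated;
  # orthogonalised against age so the modelled structural paths stay exact
  lk <- params$sbp_link
  c_raw <- ifelse(bp_med,
                  -lk$medicated * pmax(sbp_true - lk$plateau, 0) /
                    lk$med_scale,
                  -lk$unmedicated * sbp_core)
  c_orth <- stats::lm.fit(cbind(1, z_age), c_raw)$residuals
  psi_ef <- sc$psi[["ef"]]
  v_link <- stats::var(c_orth)
  if (v_link >= psi_ef)
    stop("sbp_link too strong for the executive-function residual variance")
  ef <- st[["gm_ef"]] * gm + st[["wm_ef"]] * wm + c_orth +
    sqrt(psi_ef - v_link) * stats::rnorm(n)

  # -- indicators (standardised scale, then raw mapping) --------------------
  lam <- params$loadings
  gm_names <- names(lam$gm)
  U <- diag(1 - lam$gm^2)
  dimnames(U) <- list(gm_names, gm_names)
  U["ag", "prc"] <- U["prc", "ag"] <- params$resid_cov[["ag~~prc"]]
  U["sfg", "fp"] <- U["fp", "sfg"] <- params$resid_cov[["sfg~~fp"]]
  eps_gm <- matrix(stats::rnorm(n * 6), n, 6) %*% chol(U)
  z_vol <- outer(gm, lam$gm) + eps_gm
  colnames(z_vol) <- gm_names

  z_icvf <- lam$wm[["icvf"]] * wm +
    sqrt(1 - lam$wm[["icvf"]]^2) * stats::rnorm(n)
  z_od_int <- lam$wm[["od"]] * wm +
    sqrt(1 - lam$wm[["od"]]^2) * stats::rnorm(n)
  rt_score <- lam$ef[["rt"]] * ef +
    sqrt(1 - lam$ef[["rt"]]^2) * stats::rnorm(n)
  pairs_score <- lam$ef[["pairs"]] * ef +
    sqrt(1 - lam$ef[["pairs"]]^2) * stats::rnorm(n)

  wp <- params$wmh
  cohort$wmh_mm3 <- pmax(wp$croot_mean + wp$croot_sd * z_wmh, 0.3)^3
  vols <- params$volumes
  for (v in gm_names)
    cohort[[paste0("vol_", v)]] <- vols$mean[[v]] + vols$sd[[v]] * z_vol[, v]
  nod <- params$noddi
  cohort$slf_icvf <- nod$icvf_mean + nod$icvf_sd * z_icvf
  # larger orientation dispersion = less coherent tracts, so the raw OD
  # decreases with white-matter integrity
  cohort$slf_od <- nod$od_mean - nod$od_sd * z_od_int

  # -- reaction-time trials -------------------------------------------------
  rp <- params$rt
  m_i <- pmax(rp$mean - rp$sd * rt_score, rp$floor)
  k <- rp$trials
  w <- matrix(stats::rlnorm(n * k, -rp$sdlog^2 / 2, rp$sdlog), n, k)
  w <- pmin(w, 1.8)
  outlier <- matrix(stats::runif(n * k) < rp$outlier_frac, n, k)
  outlier[rowSums(!outlier) == 0L, ] <- FALSE  # keep >= 1 valid trial
  w_valid <- w; w_valid[outlier] <- NA
  w_norm <- w_valid / rowMeans(w_valid, na.rm = TRUE)
  trials <- w_norm * m_i
  trials <- pmin(trials, 1995)               # safety: stay in valid window
  n_out <- sum(outlier)
  if (n_out) {
    low <- stats::runif(n_out) < 0.5
    ov <- numeric(n_out)
    ov[low] <- stats::runif(sum(low), 20, 49)
    ov[!low] <- stats::runif(sum(!low), 2005, 3200)
    trials[outlier] <- ov
  }
  colnames(trials) <- paste0("rt_trial_", sprintf("%02d", seq_len(k)))
  cohort <- cbind(cohort, as.data.frame(trials))

  # -- pairs-matching errors: over-dispersed counts, monotone in the score --
  pp <- params$pairs
  cohort$pairs_errors <- stats::qnbinom(stats::pnorm(-pairs_score),
                                        size = pp$size, mu = pp$mu)

  if (params$missing_rate > 0)
    cohort <- inject_missingness(cohort, params$missing_rate,
                                 seed = seed + 1L)

  attr(cohort, "params") <- params
  attr(cohort, "seed") <- seed
  cohort
}

#' Inject missing-at-random cells
#'
#' Cell-level missingness whose probability depends only on (always
#' observed) age: the per-participant rate is proportional to
#' `plogis(1.2 * z_age)`, rescaled so the expected overall rate equals
#' `rate`. Applied independently to each eligible column.
#'
#' @param table Cohort data frame with `age_at_scan`.
#' @param rate Target cell-missingness rate in `[0, 1)`.
#' @param seed RNG seed.
#' @param columns Eligible columns (defaults to the imaging and cognitive
#'   fields, leaving demographics and risk factors complete).
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed,
                               columns = c("wmh_mm3", "slf_icvf", "slf_od",
                                           "pairs_errors")) {
  if (rate < 0 || rate >= 1)
    stop("inject_missingness: rate must be in [0, 1)")
  if (rate == 0) return(table)
  if (missing(seed)) stop("inject_missingness: a seed is required")
  columns <- intersect(columns, names(table))
  set.seed(seed)
  z_age <- as.vector(scale(table$age_at_scan))
  wgt <- stats::plogis(1.2 * z_age)
  p_i <- pmin(rate * wgt / mean(wgt), 0.95)
  for (cc in columns) {
    hit <- stats::runif(nrow(table)) < p_i
    table[[cc]][hit] <- NA
  }
  table
}

#' Write a cohort with a provenance sidecar
#'
#' @param cohort [generate_cohort()] output.
#' @param path Output CSV path; a JSON sidecar (params, seed, package
#'   version) is written next to it.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", "_provenance.json", path)
  jsonlite::write_json(
    list(seed = attr(cohort, "seed"), n = nrow(cohort),
         package_version = as.character(utils::packageVersion("cvrsem")),
         params = attr(cohort, "params")),
    sidecar, digits = NA, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(path)
}
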