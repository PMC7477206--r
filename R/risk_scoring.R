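#' Cerebrovascular risk (CVR) scoring
#'
#' A rule-based sum score of cerebrovascular risk components: measured
#' hypertension, blood-pressure and cholesterol medication, diagnosed
#' diabetes, high waist-to-hip ratio, smoking exposure (pack-years) and
#' APOE epsilon-4 carriage. The total ranges 0-9.
#'
#' @name risk_scoring
NULL

#' Default scoring thresholds
#'
#' Hypertension thresholds follow NICE definitions (140/90 mmHg, inclusive);
#' waist-to-hip cut-offs follow the WHO 2008 report (0.90 men, 0.85 women,
#' inclusive); the pack-year band [10, 50] contributes 1 point and > 50
#' contributes 2. All boundaries are inclusive and collected here so a user
#' can supply a modified set.
#'
#' @return Named list of scoring constants.
#' @export
cvr_thresholds <- function() {
  list(
    sbp = 140, dbp = 90,
    whr = c(male = 0.90, female = 0.85),
    pack_year_band = c(10, 50)
  )
}

#' Mean blood pressure across repeat readings
#'
#' @param readings Numeric vector of mmHg readings (typically two, taken
#'   moments apart). A single reading is returned unchanged.
#' @return Arithmetic mean in mmHg.
#' @export
mean_bp <- function(readings) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0L)
    stop("mean_bp: no blood-pressure readings available (missing data)")
  if (any(readings <= 0)) stop("mean_bp: readings must be positive mmHg")
  mean(readings)
}

#' Measured hypertension flag
#'
#' Both the systolic and the diastolic averages must reach threshold
#' (140/90 mmHg by default, inclusive) for a participant to be classified
#' hypertensive.
#'
#' @param sbp,dbp Averaged systolic/diastolic pressure, mmHg. Vectorised.
#' @param thresholds Scoring constants, see [cvr_thresholds()].
#' @return Logical vector.
#' @export
is_hypertensive <- function(sbp, dbp, thresholds = cvr_thresholds()) {
  if (any(sbp <= 0, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE))
    stop("is_hypertensive: blood pressures must be positive")
  sbp >= thresholds$sbp & dbp >= thresholds$dbp
}

#' Waist-to-hip ratio above the sex-specific cut-off
#'
#' @param waist_cm,hip_cm Circumferences in cm, positive. Vectorised.
#' @param sex Character vector, "male" or "female".
#' @param thresholds Scoring constants, see [cvr_thresholds()].
#' @return Logical vector (inclusive comparison).
#' @export
whr_exceeds_threshold <- function(waist_cm, hip_cm, sex,
                                  thresholds = cvr_thresholds()) {
  if (any(hip_cm <= 0, na.rm = TRUE))
    stop("whr_exceeds_threshold: hip circumference must be positive")
  if (any(waist_cm <= 0, na.rm = TRUE))
    stop("whr_exceeds_threshold: waist circumference must be positive")
  sex <- match_sex(sex)
  cut <- unname(thresholds$whr[sex])
  waist_cm / hip_cm >= cut
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad)) stop("sex must be 'male' or 'female'")
  sex
}

#' Smoking exposure in pack-years
#'
#' Daily cigarettes divided by 20 (a pack), times years smoked. The exposure
#' window ends at the age smoking stopped for ex-smokers, or at the age at
#' scan for current smokers.
#'
#' @param cigs_per_day Cigarettes per day, >= 0. Vectorised.
#' @param age_started,age_end Years; `age_end >= age_started`.
#' @return Pack-years, >= 0.
#' @export
pack_years <- function(cigs_per_day, age_started, age_end) {
  if (any(cigs_per_day < 0, na.rm = TRUE))
    stop("pack_years: cigarettes per day must be non-negative")
  if (any(age_end < age_started, na.rm = TRUE))
    stop("pack_years: smoking end age precedes start age")
  (cigs_per_day / 20) * (age_end - age_started)
}

#' Points contributed by smoking history
#'
#' Never-smokers score 0; 10-50 pack-years (inclusive band) scores 1;
#' more than 50 scores 2; under 10 scores 0.
#'
#' @param status Character vector: "never", "ex" or "current".
#' @param pack_years Pack-years of exposure (ignored for never-smokers; may
#'   be `NA` for never-smokers).
#' @param thresholds Scoring constants, see [cvr_thresholds()].
#' @return Integer vector in 0..2.
#' @export
smoking_points <- function(status, pack_years = NA_real_,
                           thresholds = cvr_thresholds()) {
  status <- tolower(as.character(status))
  bad <- !is.na(status) & !status %in% c("never", "ex", "current")
  if (any(bad)) stop("smoking status must be 'never', 'ex' or 'current'")
  if (any(pack_years < 0, na.rm = TRUE))
    stop("smoking_points: negative pack-years")
  band <- thresholds$pack_year_band
  pts <- ifelse(pack_years > band[2], 2L,
         ifelse(pack_years >= band[1], 1L, 0L))
  pts[!is.na(status) & status == "never"] <- 0L
  pts
}

#' Points contributed by APOE genotype
#'
#' One point per epsilon-4 allele: e3/e3 (and any genotype without e4)
#' scores 0, heterozygous e4 carriers 1, e4/e4 homozygotes 2.
#'
#' @param genotype Character vector like `"e3/e4"`; alleles drawn from
#'   e2, e3, e4 in either order. The Greek spelling ("ε3/ε4") is accepted.
#' @return Integer vector in 0..2.
#' @export
apoe_points <- function(genotype) {
  g <- tolower(gsub("ε", "e", as.character(genotype)))
  parse_one <- function(x) {
    if (is.na(x)) return(NA_integer_)
    alleles <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c("e2", "e3", "e4")))
      stop("apoe_points: unknown genotype label '", x, "'")
    sum(alleles == "e4")
  }
  vapply(g, parse_one, integer(1), USE.NAMES = FALSE)
}

#' Score one participant's cerebrovascular risk factors
#'
#' Sums the seven component scores. A component whose inputs are missing is
#' treated as 0 and flagged (sum-score convention); set
#' `na_action = "propagate"` to return `NA` totals instead.
#'
#' @param rf A list or one-row data frame with fields `sbp_readings`,
#'   `dbp_readings` (numeric vectors), `on_bp_medication`,
#'   `on_cholesterol_medication`, `diabetic` (logical), `sex`, `waist_cm`,
#'   `hip_cm`, `smoking_status`, `cigarettes_per_day`, `age_started_smoking`,
#'   `age_stopped_smoking`, `age_at_scan`, `apoe_genotype`.
#' @param thresholds Scoring constants, see [cvr_thresholds()].
#' @param na_action `"zero"` (default) or `"propagate"`.
#' @return A list of class `cvr_breakdown` with one 0/1 (or 0-2) entry per
#'   component, `total`, and `missing` (character vector of missing
#'   components).
#' @export
cvr_score <- function(rf, thresholds = cvr_thresholds(),
                      na_action = c("zero", "propagate")) {
  na_action <- match.arg(na_action)
  missing_components <- character(0)
  grab <- function(name) if (name %in% names(rf)) rf[[name]] else NULL

  comp <- function(name, value) {
    if (is.null(value) || length(value) == 0L || all(is.na(value))) {
      missing_components <<- c(missing_components, name)
      if (na_action == "zero") 0L else NA_integer_
    } else as.integer(value)
  }

  hyp <- tryCatch({
    sbp <- mean_bp(grab("sbp_readings"))
    dbp <- mean_bp(grab("dbp_readings"))
    is_hypertensive(sbp, dbp, thresholds)
  }, error = function(e) NA)
  hypertensive_point <- comp("hypertension", hyp)

  bp_med_point   <- comp("bp_medication", grab("on_bp_medication"))
  chol_med_point <- comp("cholesterol_medication",
                         grab("on_cholesterol_medication"))
  diabetes_point <- comp("diabetes", grab("diabetic"))

  whr <- tryCatch(
    whr_exceeds_threshold(grab("waist_cm"), grab("hip_cm"), grab("sex"),
                          thresholds),
    error = function(e) NA)
  whr_point <- comp("whr", whr)

  smk <- tryCatch({
    status <- grab("smoking_status")
    if (is.null(status) || is.na(status)) NA_integer_
    else if (tolower(status) == "never") 0L
    else {
      end_age <- if (tolower(status) == "current") grab("age_at_scan")
                 else grab("age_stopped_smoking")
      py <- pack_years(grab("cigarettes_per_day"),
                       grab("age_started_smoking"), end_age)
      smoking_points(status, py, thresholds)
    }
  }, error = function(e) NA_integer_)
  smoking_pts <- comp("smoking", smk)

  apoe <- tryCatch(apoe_points(grab("apoe_genotype")),
                   error = function(e) NA_integer_)
  apoe_pts <- comp("apoe", apoe)

  parts <- c(hypertensive_point = hypertensive_point,
             bp_med_point = bp_med_point,
             chol_med_point = chol_med_point,
             diabetes_point = diabetes_point,
             whr_point = whr_point,
             smoking_points = smoking_pts,
             apoe_points = apoe_pts)
  if (length(missing_components) == 7L)
    stop("cvr_score: all components missing, score undefined")
  out <- c(as.list(parts),
           list(total = sum(parts), missing = missing_components))
  class(out) <- "cvr_breakdown"
  out
}

#' @export
print.cvr_breakdown <- function(x, ...) {
  cat("CVR breakdown (total ", x$total, "/9)\n", sep = "")
  comp <- unlist(x[setdiff(names(x), c("total", "missing"))])
  print(comp)
  if (length(x$missing))
    cat("missing components treated as 0:",
        paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Score a whole cohort table
#'
#' Vectorised scoring over a cohort data frame with the column dictionary
#' used throughout the package: `sbp_1`, `sbp_2`, `dbp_1`, `dbp_2`,
#' `on_bp_medication`, `on_cholesterol_medication`, `diabetic`, `sex`,
#' `waist_cm`, `hip_cm`, `smoking_status`, `cigarettes_per_day`,
#' `age_started_smoking`, `age_stopped_smoking`, `age_at_scan`,
#' `apoe_genotype`. Missing components score 0 and are counted in
#' `n_missing_components`.
#'
#' @param cohort Data frame, one participant per row.
#' @param thresholds Scoring constants, see [cvr_thresholds()].
#' @return Data frame with one column per component, `total`, and
#'   `n_missing_components`.
#' @export
score_cohort <- function(cohort, thresholds = cvr_thresholds()) {
  n <- nrow(cohort)
  sbp <- rowMeans(cbind(cohort$sbp_1, cohort$sbp_2), na.rm = TRUE)
  dbp <- rowMeans(cbind(cohort$dbp_1, cohort$dbp_2), na.rm = TRUE)
  sbp[is.nan(sbp)] <- NA; dbp[is.nan(dbp)] <- NA
  hyp <- sbp >= thresholds$sbp & dbp >= thresholds$dbp

  whr <- whr_exceeds_threshold(cohort$waist_cm, cohort$hip_cm, cohort$sex,
                               thresholds)

  status <- tolower(as.character(cohort$smoking_status))
  end_age <- ifelse(status == "current", cohort$age_at_scan,
                    cohort$age_stopped_smoking)
  py <- ifelse(status == "never", 0,
               (cohort$cigarettes_per_day / 20) *
                 pmax(end_age - cohort$age_started_smoking, 0))
  smk <- smoking_points(status, py, thresholds)

  apoe <- apoe_points(cohort$apoe_genotype)

  zero_na <- function(x) {
    x <- as.integer(x)
    miss <- is.na(x)
    x[miss] <- 0L
    list(x = x, miss = miss)
  }
  comps <- list(
    hypertensive_point = zero_na(hyp),
    bp_med_point       = zero_na(cohort$on_bp_medication),
    chol_med_point     = zero_na(cohort$on_cholesterol_medication),
    diabetes_point     = zero_na(cohort$diabetic),
    whr_point          = zero_na(whr),
    smoking_points     = zero_na(smk),
    apoe_points        = zero_na(apoe)
  )
  out <- as.data.frame(lapply(comps, `[[`, "x"))
  out$total <- rowSums(out)
  out$n_missing_components <- rowSums(vapply(comps, `[[`, logical(n), "miss"))
  out
}

#' Write a per-participant CVR breakdown table
#'
#' @param breakdown Output of [score_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cvr_breakdown <- function(breakdown, path) {
  utils::write.table(breakdown, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
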