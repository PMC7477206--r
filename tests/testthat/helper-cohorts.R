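# cohorts are expensive to generate; memoise per (n, seed, rate) within a run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n, seed, missing_rate = 0) {
  key <- paste(n, seed, missing_rate, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(
      cohort_params(n = n, missing_rate = missing_rate), seed = seed)
  .cohort_cache[[key]]
}

cached_analysis <- function(n, seed, missing_rate = 0) {
  key <- paste("an", n, seed, missing_rate, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <-
      prepare_analysis_table(cached_cohort(n, seed, missing_rate))
  .cohort_cache[[key]]
}

# a minimal complete risk-factor record, overridable by field
risk_record <- function(...) {
  rec <- list(
    sbp_readings = c(118, 122), dbp_readings = c(74, 76),
    on_bp_medication = FALSE, on_cholesterol_medication = FALSE,
    diabetic = FALSE, sex = "female", waist_cm = 80, hip_cm = 100,
    smoking_status = "never", cigarettes_per_day = NA,
    age_started_smoking = NA, age_stopped_smoking = NA,
    age_at_scan = 60, apoe_genotype = "e3/e3")
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}
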