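test_that("blood-pressure averaging handles repeats, singles and missing", {
  expect_equal(mean_bp(c(120, 130)), 125)
  expect_equal(mean_bp(118), 118)
  expect_error(mean_bp(numeric(0)), "missing")
  expect_error(mean_bp(c(NA, NA)), "missing")
})

test_that("hypertension needs both readings at threshold, inclusively", {
  expect_true(is_hypertensive(145, 95))
  expect_false(is_hypertensive(150, 85))
  expect_false(is_hypertensive(135, 95))
  expect_true(is_hypertensive(140, 90))
  expect_error(is_hypertensive(-1, 90), "positive")
})

test_that("waist-to-hip cut-offs are sex-specific and inclusive", {
  expect_true(whr_exceeds_threshold(95, 100, "male"))
  expect_false(whr_exceeds_threshold(84, 100, "female"))
  expect_true(whr_exceeds_threshold(85, 100, "female"))
  expect_false(whr_exceeds_threshold(89, 100, "male"))
  expect_true(whr_exceeds_threshold(90, 100, "male"))
  expect_error(whr_exceeds_threshold(85, 0, "male"), "positive")
  expect_error(whr_exceeds_threshold(85, 100, "other"), "sex")
})

test_that("pack-years follow the cigarettes/20 times duration rule", {
  expect_equal(pack_years(20, 20, 30), 10)
  expect_equal(pack_years(40, 25, 55), 60)
  expect_equal(pack_years(10, 30, 30), 0)
  expect_error(pack_years(10, 40, 30), "precede")
  expect_error(pack_years(-5, 20, 30), "non-negative")
})

test_that("smoking points follow the 10-50 / >50 pack-year bands", {
  expect_equal(smoking_points("ex", 30), 1L)
  expect_equal(smoking_points("current", 60), 2L)
  expect_equal(smoking_points("never"), 0L)
  expect_equal(smoking_points("ex", 9.99), 0L)
  expect_equal(smoking_points("ex", 10), 1L)
  expect_equal(smoking_points("ex", 50), 1L)
  expect_equal(smoking_points("ex", 50.01), 2L)
  expect_error(smoking_points("ex", -1), "negative")
  # monotone non-decreasing step function
  grid <- seq(0, 80, by = 0.5)
  pts <- smoking_points(rep("ex", length(grid)), grid)
  expect_true(all(diff(pts) >= 0))
})

test_that("APOE points equal the e4 allele count over all genotypes", {
  genos <- c("e2/e2", "e2/e3", "e3/e3", "e2/e4", "e3/e4", "e4/e4")
  expect_equal(apoe_points(genos), c(0L, 0L, 0L, 1L, 1L, 2L))
  expect_equal(apoe_points("e4/e3"), 1L) # order-free
  expect_equal(apoe_points("ε3/ε4"), 1L) # Greek spelling
  expect_error(apoe_points("e3/e5"), "unknown genotype")
})

test_that("CVR total spans 0-9 and equals the component sum", {
  expect_equal(cvr_score(risk_record())$total, 0)

  three <- cvr_score(risk_record(
    sbp_readings = c(150, 150), dbp_readings = c(95, 95),
    on_bp_medication = TRUE, diabetic = TRUE))
  expect_equal(three$total, 3)

  maximal <- cvr_score(risk_record(
    sbp_readings = c(160, 160), dbp_readings = c(100, 100),
    on_bp_medication = TRUE, on_cholesterol_medication = TRUE,
    diabetic = TRUE, waist_cm = 110, hip_cm = 100,
    smoking_status = "current", cigarettes_per_day = 40,
    age_started_smoking = 20, age_at_scan = 60,
    apoe_genotype = "e4/e4"))
  expect_equal(maximal$total, 9)
})

test_that("randomly generated records satisfy total == sum of components", {
  set.seed(42)
  for (i in 1:50) {
    rec <- risk_record(
      sbp_readings = runif(2, 100, 180), dbp_readings = runif(2, 60, 110),
      on_bp_medication = runif(1) < 0.5,
      on_cholesterol_medication = runif(1) < 0.5,
      diabetic = runif(1) < 0.5,
      sex = sample(c("male", "female"), 1),
      waist_cm = runif(1, 60, 120), hip_cm = runif(1, 80, 130),
      smoking_status = sample(c("never", "ex", "current"), 1),
      cigarettes_per_day = sample(1:60, 1),
      age_started_smoking = sample(14:25, 1),
      age_stopped_smoking = sample(30:55, 1),
      age_at_scan = sample(56:73, 1),
      apoe_genotype = sample(c("e2/e2", "e2/e3", "e3/e3", "e2/e4", "e3/e4",
                               "e4/e4"), 1))
    br <- cvr_score(rec)
    comps <- unlist(br[c("hypertensive_point", "bp_med_point",
                         "chol_med_point", "diabetes_point", "whr_point",
                         "smoking_points", "apoe_points")])
    expect_equal(br$total, sum(comps))
    expect_true(br$total >= 0 && br$total <= 9)
    expect_true(all(comps >= 0 & comps <= c(1, 1, 1, 1, 1, 2, 2)))
  }
})

test_that("missing components score zero with a flag, or propagate", {
  rec <- risk_record(apoe_genotype = NA, waist_cm = NA)
  br <- cvr_score(rec)
  expect_equal(br$total, 0)
  expect_setequal(br$missing, c("apoe", "whr"))
  br2 <- cvr_score(rec, na_action = "propagate")
  expect_true(is.na(br2$total))
  rec_none <- lapply(risk_record(), function(x) NA)
  expect_error(cvr_score(rec_none), "all components missing")
})

test_that("vectorised cohort scoring agrees with the single-record scorer", {
  co <- cached_cohort(300, 2)
  br <- score_cohort(co)
  expect_equal(br$total,
               rowSums(br[, setdiff(names(br),
                                    c("total", "n_missing_components"))]))
  for (i in c(1, 57, 300)) {
    rec <- risk_record(
      sbp_readings = c(co$sbp_1[i], co$sbp_2[i]),
      dbp_readings = c(co$dbp_1[i], co$dbp_2[i]),
      on_bp_medication = co$on_bp_medication[i],
      on_cholesterol_medication = co$on_cholesterol_medication[i],
      diabetic = co$diabetic[i], sex = co$sex[i],
      waist_cm = co$waist_cm[i], hip_cm = co$hip_cm[i],
      smoking_status = co$smoking_status[i],
      cigarettes_per_day = co$cigarettes_per_day[i],
      age_started_smoking = co$age_started_smoking[i],
      age_stopped_smoking = co$age_stopped_smoking[i],
      age_at_scan = co$age_at_scan[i],
      apoe_genotype = co$apoe_genotype[i])
    expect_equal(br$total[i], cvr_score(rec)$total)
  }
})
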