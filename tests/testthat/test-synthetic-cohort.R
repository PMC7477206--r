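test_that("generation is bit-reproducible and n = 0 yields the dictionary", {
  p <- cohort_params(n = 150)
  a <- generate_cohort(p, seed = 31)
  b <- generate_cohort(p, seed = 31)
  attributes(a) <- attributes(b) <- NULL
  expect_identical(a, b)
  c2 <- generate_cohort(p, seed = 32)
  expect_false(identical(a[[2]], c2$age_at_scan))

  empty <- generate_cohort(cohort_params(n = 0), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("age_at_scan", "sbp_1", "apoe_genotype", "wmh_mm3",
                    "rt_trial_01", "pairs_errors") %in% names(empty)))
  expect_error(generate_cohort(cohort_params(n = 10)), "seed")
})

test_that("marginals land on the calibrated population targets", {
  co <- cached_cohort(8000, 33)
  n <- nrow(co)
  se3 <- 3 * sqrt(0.76 * 0.24 / n)
  expect_lt(abs(mean(co$apoe_genotype == "e3/e3") - 0.76), se3)
  expect_lt(abs(mean(co$diabetic) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_lt(abs(mean(co$on_cholesterol_medication) - 0.21),
            3 * sqrt(0.21 * 0.79 / n))
  expect_lt(abs(mean(co$on_bp_medication) - 0.22),
            3 * sqrt(0.22 * 0.78 / n))
  expect_lt(abs(mean(co$smoking_status == "never") - 0.78),
            3 * sqrt(0.78 * 0.22 / n))
  expect_lt(abs(mean(co$age_at_scan) - 62), 0.25)
  expect_lt(abs(sd(co$age_at_scan) - 7), 0.25)
  expect_true(all(co$age_at_scan >= 44 & co$age_at_scan <= 73))
  # age gradient of the score close to the stated exogenous covariance
  expect_lt(abs(cor(co$age_at_scan, score_cohort(co)$total) - 0.25), 0.05)
})

test_that("ground truth is internally consistent and positive definite", {
  gt <- ground_truth()
  expect_s3_class(gt$spec, "sem_spec")
  Sig <- implied_covariance(gt$spec, unname(gt$theta))
  expect_gt(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  # standardised-scale theta: implied variances are exactly 1
  expect_equal(unname(diag(Sig)), rep(1, 13), tolerance = 1e-12)
  # round trip: injected coefficients are the structural parameters
  st <- cohort_params()$structural
  expect_equal(gt$theta[["wmh~cvr"]], st[["cvr_wmh"]])
  expect_equal(gt$theta[["ef~wm"]], st[["wm_ef"]])
  expect_equal(gt$theta[["ef=~rt"]], 0.49)
  expect_equal(gt$Sigma_structural["age", "cvr"], st[["age_cvr"]])
  # an infeasible coefficient set is rejected with the offending block named
  bad <- cohort_params(structural = c(gm_ef = 0.9, wm_ef = 0.9))
  expect_error(ground_truth(bad), "residual variance")
})

test_that("the analysis-scale correlations approach the implied covariance", {
  co <- cached_cohort(100000, 34)
  an <- prepare_analysis_table(co)
  gt <- ground_truth()
  Sig <- implied_covariance(gt$spec, unname(gt$theta))
  emp <- cor(an)
  # the count-valued pairs indicator is discretised, attenuating its row
  no_pairs <- setdiff(rownames(Sig), "pairs")
  expect_lt(max(abs(emp[no_pairs, no_pairs] - Sig[no_pairs, no_pairs])),
            0.015)
  expect_lt(max(abs(emp["pairs", no_pairs] - Sig["pairs", no_pairs])), 0.05)
})

test_that("reaction-time trials contain the configured outlier fraction", {
  co <- cached_cohort(8000, 33)
  trials <- as.matrix(co[grep("^rt_trial_", names(co))])
  out_frac <- mean(trials < 50 | trials > 2000)
  expect_lt(abs(out_frac - 0.02), 3 * sqrt(0.02 * 0.98 / length(trials)))
  # every participant keeps at least one valid trial
  expect_true(all(rowSums(trials >= 50 & trials <= 2000) >= 1))
  # WMH volumes are right-skewed, cube root roughly symmetric
  sk <- function(x) mean(((x - mean(x)) / sd(x))^3)
  expect_gt(sk(co$wmh_mm3), 0.5)
  expect_lt(abs(sk(co$wmh_mm3^(1 / 3))), 0.2)
})

test_that("missingness injection is MAR on age at the requested rate", {
  co <- cached_cohort(8000, 33)
  expect_identical(inject_missingness(co, 0, seed = 1), co)
  miss <- inject_missingness(co, 0.2, seed = 35)
  cols <- c("wmh_mm3", "slf_icvf", "slf_od", "pairs_errors")
  rate <- mean(is.na(as.matrix(miss[cols])))
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / (nrow(co) * 4)))
  # probability increases with age (missing-at-random on an observed field)
  is_miss <- is.na(miss$wmh_mm3)
  expect_gt(mean(miss$age_at_scan[is_miss]),
            mean(miss$age_at_scan[!is_miss]))
  expect_error(inject_missingness(co, 1.0, seed = 1), "rate")
})

test_that("cohorts round-trip through the CSV writer with provenance", {
  co <- cached_cohort(150, 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 150)
  expect_equal(back$wmh_mm3, co$wmh_mm3, tolerance = 1e-12)
  prov <- jsonlite::read_json(sub("\\.csv$", "_provenance.json", path))
  expect_equal(prov$seed, 31)
  expect_equal(prov$n, 150)
})
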