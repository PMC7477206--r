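test_that("reaction-time filtering keeps the inclusive 50-2000 ms window", {
  expect_equal(filter_rt_trials(c(45, 300, 2500)), 300)
  expect_equal(filter_rt_trials(c(50, 2000)), c(50, 2000))
  expect_equal(filter_rt_trials(numeric(0)), numeric(0))
  expect_equal(filter_rt_trials(c(49.999, 2000.001)), numeric(0))
  # order preserved
  expect_equal(filter_rt_trials(c(900, 100, 3000, 500)), c(900, 100, 500))
})

test_that("mean RT averages surviving trials and errors when none survive", {
  expect_equal(mean_rt(c(300, 500)), 400)
  expect_equal(mean_rt(rep(400, 12)), 400)
  expect_error(mean_rt(filter_rt_trials(c(45, 45))), "missing")
})

test_that("filter-then-mean is invariant to trial order", {
  set.seed(7)
  for (i in 1:20) {
    trials <- c(runif(10, 10, 2500))
    expect_equal(mean_rt(filter_rt_trials(trials)),
                 mean_rt(filter_rt_trials(sample(trials))))
  }
})

test_that("MAD normalisation centres at 0 with the 1.4826 constant", {
  out <- mad_normalize(c(1, 2, 3))
  expect_equal(as.vector(out), c(-1, 0, 1) / 1.4826, tolerance = 1e-12)
  expect_equal(as.vector(out)[3], 0.6744907, tolerance = 1e-6)
  expect_error(mad_normalize(rep(5, 10), name = "flat"), "flat")
  set.seed(1)
  x <- rexp(101)
  expect_equal(median(as.vector(mad_normalize(x))), 0)
  # raw-MAD option
  expect_equal(as.vector(mad_normalize(c(1, 2, 3), constant = 1)),
               c(-1, 0, 1))
})

test_that("MAD normalisation is affine-equivariant", {
  set.seed(2)
  x <- rnorm(51)
  z <- as.vector(mad_normalize(x))
  expect_equal(as.vector(mad_normalize(3 * x - 7)), z, tolerance = 1e-10)
  expect_equal(as.vector(mad_normalize(-2 * x + 1)), -z, tolerance = 1e-10)
})

test_that("cube-root transform is exact and rejects negative volumes", {
  expect_equal(cube_root_wmh(27), 3)
  expect_equal(cube_root_wmh(0), 0)
  expect_equal(cube_root_wmh(1000), 10)
  expect_error(cube_root_wmh(-1), "negative")
})

test_that("confound residualisation matches a normal-equations oracle", {
  set.seed(3)
  C <- matrix(rnorm(20 * 3), 20, 3)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  R <- residualize_confounds(Y, C)
  # independent two-stage oracle: solve the normal equations by hand
  X <- cbind(1, C)
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(R, Y - X %*% beta, tolerance = 1e-10, ignore_attr = TRUE)
  # orthogonality to confounds and intercept
  expect_lt(max(abs(t(R) %*% X)), 1e-8)
  # idempotence
  expect_equal(residualize_confounds(R, C), R, tolerance = 1e-10)
  # Y exactly linear in C -> zero residuals
  Ylin <- X %*% matrix(1:8, 4, 2)
  expect_lt(max(abs(residualize_confounds(Ylin, C))), 1e-10)
  # rank-deficient confounds
  expect_error(residualize_confounds(Y, cbind(C, C[, 1])),
               "rank deficient")
})

test_that("analysis table is normalised, oriented and complete", {
  co <- cached_cohort(400, 4)
  an <- prepare_analysis_table(co)
  expect_named(an, c("age", "cvr", "wmh", "ag", "prc", "cg", "sfg", "fp",
                     "mtg", "icvf", "od", "rt", "pairs"))
  meds <- vapply(an, median, numeric(1))
  expect_lt(max(abs(meds)), 1e-10)
  # rt column: negated affine image of the filtered trial means
  trials <- as.matrix(co[grep("^rt_trial_", names(co))])
  trials[trials < 50 | trials > 2000] <- NA
  expect_equal(cor(an$rt, rowMeans(trials, na.rm = TRUE)), -1,
               tolerance = 1e-12)
  # od negated: raw orientation dispersion correlates negatively
  expect_equal(cor(an$od, co$slf_od), -1, tolerance = 1e-12)
  # wmh column is the normalised cube root
  expect_equal(cor(an$wmh, co$wmh_mm3^(1 / 3)), 1, tolerance = 1e-12)
  sidecar <- attr(an, "normalization")
  expect_equal(sidecar$variable, names(an))
  expect_true(all(sidecar$scale > 0))
  expect_match(sidecar$transform[sidecar$variable == "wmh"], "cube_root")
  # unflipped mode keeps recorded orientation
  an_raw <- prepare_analysis_table(co, flip = FALSE)
  expect_equal(cor(an_raw$od, co$slf_od), 1, tolerance = 1e-12)
})
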