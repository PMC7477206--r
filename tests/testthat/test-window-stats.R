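test_that("sliding windows match brute-force enumeration on sorted data", {
  set.seed(19)
  x <- rnorm(10); y <- rnorm(10)
  cur <- sliding_window_curve(x, y, frac = 0.5, step_quantile = 0.1)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  # exhaustive oracle: all 6 contiguous 5-element windows
  expect_equal(nrow(cur), 6)
  for (k in 1:6) {
    idx <- k:(k + 4)
    expect_equal(cur$mean[k], mean(ys[idx]))
    expect_equal(cur$center[k], median(xs[idx]))
    expect_equal(cur$sem[k], sd(ys[idx]) / sqrt(5))
    expect_equal(cur$count[k], 5)
  }
})

test_that("sliding-window defaults give 91 windows with sane shapes", {
  set.seed(20)
  n <- 2000
  x <- rnorm(n, 138, 18)
  cur_const <- sliding_window_curve(x, rep(3, n))
  expect_equal(nrow(cur_const), 91)
  expect_true(all(abs(cur_const$mean - 3) < 1e-12))
  cur_lin <- sliding_window_curve(x, x)
  expect_true(all(diff(cur_lin$mean) > 0))
  expect_true(all(diff(cur_lin$center) >= 0))
  # invariance to row order
  perm <- sample(n)
  cur_perm <- sliding_window_curve(x[perm], x[perm])
  expect_equal(cur_perm$mean, cur_lin$mean)
  expect_error(sliding_window_curve(1:5, 1:5, frac = 0.1), "at least")
})

test_that("Gaussian smoothing conserves mass and passes linear signals", {
  expect_equal(gaussian_smooth(rep(2, 50), 10), rep(2, 50))
  imp <- c(rep(0, 60), 1, rep(0, 60))
  expect_equal(sum(gaussian_smooth(imp, 5)), 1, tolerance = 1e-9)
  ramp <- seq(0, 10, length.out = 120)
  sm <- gaussian_smooth(ramp, 5)
  interior <- 25:96  # beyond the 4-sigma truncation from either edge
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-8)
  # never extends the range
  set.seed(21)
  y <- rnorm(80)
  sm2 <- gaussian_smooth(y, 10)
  expect_gte(min(sm2), min(y))
  expect_lte(max(sm2), max(y))
  expect_equal(gaussian_smooth(numeric(0), 10), numeric(0))
  expect_error(gaussian_smooth(1:5, 0), "positive")
})

test_that("fixed-width bins report means and flag empty bins", {
  # all x in one bin
  one <- fixed_bin_curve(c(101, 102, 103), c(1, 2, 3), n_bins = 10,
                         width = 16)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean, 2)
  # y = x with uniform x: bin means increase by ~ width
  set.seed(22)
  x <- runif(20000, 80, 240)
  fb <- fixed_bin_curve(x, x, n_bins = 10, width = 16)
  expect_equal(mean(diff(fb$mean)), 16, tolerance = 0.5)
  # an empty middle bin is flagged and excluded
  gap <- c(runif(100, 0, 16), runif(100, 48, 64))
  fg <- fixed_bin_curve(gap, gap, n_bins = 4, width = 16, origin = 0)
  expect_true(2 %in% attr(fg, "empty_bins"))
  expect_false(2 %in% fg$bin)
  expect_error(fixed_bin_curve(1:5, 1:5, width = 0), "positive")
})

test_that("age-quantile residuals demean within every bin", {
  set.seed(23)
  n <- 1000
  age <- runif(n, 44, 73)
  v <- 0.5 * age + rnorm(n)
  res <- age_quantile_residuals(v, age, n_bins = 10)
  bins <- attr(res, "bin")
  for (b in 1:10)
    expect_lt(abs(mean(res[bins == b])), 1e-10)
  # v an exact function of the age bin -> all residuals zero
  v2 <- as.numeric(bins)
  res2 <- age_quantile_residuals(v2, age, n_bins = 10)
  expect_lt(max(abs(res2)), 1e-12)
  expect_error(age_quantile_residuals(1:5, 1:5, n_bins = 10), "fewer cases")
})

test_that("residual correlations equal a dummy-regression partial oracle", {
  set.seed(24)
  n <- 600
  age <- runif(n, 44, 73)
  a <- 0.4 * age + rnorm(n)
  b <- -0.3 * age + rnorm(n)
  ra <- age_quantile_residuals(a, age, n_bins = 8)
  rb <- age_quantile_residuals(b, age, n_bins = 8)
  bins <- factor(attr(ra, "bin"))
  # oracle: bin fixed-effects regressions via lm
  oa <- residuals(lm(a ~ bins))
  ob <- residuals(lm(b ~ bins))
  expect_equal(cor(ra, rb), cor(oa, ob), tolerance = 1e-8)
})

test_that("a generated cohort shows the expected SBP/EF age patterns", {
  co <- cached_cohort(10000, 25)
  an <- cached_analysis(10000, 25)
  sbp <- rowMeans(co[, c("sbp_1", "sbp_2")])
  ef <- ef_sum_score(an)
  # SBP rises and executive function falls across age
  expect_gt(coef(lm(sbp ~ co$age_at_scan))[2], 0)
  expect_lt(coef(lm(ef ~ co$age_at_scan))[2], 0)
  # after age-quantile residualisation a negative SBP-EF association remains
  r_sbp <- age_quantile_residuals(sbp, co$age_at_scan)
  r_ef <- age_quantile_residuals(ef, co$age_at_scan)
  ct <- pearson_ci(r_sbp, r_ef)
  expect_lt(ct$r, 0)
  expect_lt(ct$p, 0.001)
})
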