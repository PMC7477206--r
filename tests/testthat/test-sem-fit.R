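test_that("implied covariance reproduces closed forms", {
  # single observed variable with variance 2
  s1 <- sem_spec("x")
  expect_equal(implied_covariance(s1, 2), matrix(2, dimnames = list("x", "x")))

  # y = 0.5 x, Var(x) = 1, residual 0.75 -> Var(y) = 1, Cov = 0.5
  s2 <- sem_spec(c("x", "y"), paths = data.frame(from = "x", to = "y"))
  Sig <- implied_covariance(s2, c(0.5, 1, 0.75))
  expect_equal(unname(Sig),
               matrix(c(1, 0.5, 0.5, 1), 2), tolerance = 1e-12)

  # one factor, loadings (1, lambda), factor var phi, uniques theta
  s3 <- sem_spec(c("a", "b"), latents = list(f = c("a", "b")))
  lambda <- 0.8; phi <- 2; th <- c(0.3, 0.4)
  Sig3 <- implied_covariance(s3, c(lambda, th[1], th[2], phi))
  L <- c(1, lambda)
  expect_equal(unname(Sig3), L %*% t(L) * phi + diag(th), tolerance = 1e-12)
})

test_that("ML discrepancy is zero at equality, matches the scalar form, >= 0", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
    expect_gte(ml_discrepancy(crossprod(A) + diag(3), crossprod(B) + diag(3)),
               -1e-12)
  }
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("observed path models reproduce least squares exactly", {
  set.seed(11)
  n <- 400
  x1 <- rnorm(n); x2 <- 0.4 * x1 + rnorm(n)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n, 0, 0.9)
  dat <- data.frame(x1 = x1, x2 = x2, y = y)
  spec <- sem_spec(c("x1", "x2", "y"),
                   paths = data.frame(from = c("x1", "x2"), to = c("y", "y")),
                   covariances = data.frame(a = "x1", b = "x2"))
  fit <- fit_sem(spec, data = dat)
  ols <- coef(lm(y ~ x1 + x2, dat))
  expect_equal(fit$theta[["y~x1"]], unname(ols["x1"]), tolerance = 1e-8)
  expect_equal(fit$theta[["y~x2"]], unname(ols["x2"]), tolerance = 1e-8)
  # saturated structure: chisq = 0 at df = 0
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  # standardised single-predictor path equals the Pearson correlation
  s1 <- sem_spec(c("x1", "y"), paths = data.frame(from = "x1", to = "y"))
  f1 <- fit_sem(s1, data = dat)
  std <- f1$standardized
  expect_equal(std$std[std$label == "y~x1"], cor(x1, y), tolerance = 1e-8)
})

test_that("the standardised solution is invariant to indicator rescaling", {
  an <- cached_analysis(1500, 21)
  spec <- fp_sem_spec()
  f1 <- fit_sem(spec, data = an, se = FALSE)
  an2 <- an
  an2$ag <- an2$ag * 10 + 3       # affine rescale of one indicator
  an2$rt <- an2$rt / 4
  f2 <- fit_sem(spec, data = an2, se = FALSE)
  expect_equal(f1$standardized$std, f2$standardized$std, tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-5)
})

test_that("the likelihood is invariant to observed-variable ordering", {
  an <- cached_analysis(1500, 21)
  spec <- fp_sem_spec()
  f1 <- fit_sem(spec, data = an, se = FALSE)
  perm <- rev(spec$observed)
  spec2 <- sem_spec(perm, spec$latents, spec$paths, spec$covariances)
  f2 <- fit_sem(spec2, data = an, se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-4)
  s1 <- f1$standardized; s2 <- f2$standardized
  expect_equal(s2$std[match(s1$label, s2$label)], s1$std, tolerance = 1e-6)
})

test_that("fit indices reproduce the worked example and edge cases", {
  idx <- fit_indices(100, 40, 1000, 55, 1001)
  expect_equal(unname(idx["CFI"]), 0.936508, tolerance = 1e-4)
  expect_equal(unname(idx["TLI"]), 0.912700, tolerance = 1e-4)
  expect_equal(unname(idx["RMSEA"]), 0.038730, tolerance = 1e-4)
  perfect <- fit_indices(40, 40, 1000, 55, 1001)
  expect_equal(unname(perfect["CFI"]), 1)
  expect_equal(unname(perfect["RMSEA"]), 0)
  expect_true(is.na(fit_indices(0, 0, 100, 3, 100)["RMSEA"]))
  # clipping to [0, 1]
  bad <- fit_indices(500, 5, 100, 10, 200)
  expect_gte(min(bad[c("CFI", "TLI")]), 0)
  expect_lte(max(bad[c("CFI", "TLI")]), 1)
})

test_that("chi-square difference testing enforces nesting", {
  an <- cached_analysis(1500, 21)
  full <- fit_sem(fp_sem_spec(), data = an, se = FALSE)
  # identical models -> (0, 0, 1)
  same <- chi_square_difference(full, full)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0)
  expect_equal(same$p_value, 1)
  # chi-square(4) critical value: delta 9.488 at delta_df 4 -> p ~ 0.05
  expect_equal(stats::pchisq(9.487729, 4, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  nested <- fit_sem(constrain_variable_paths(fp_sem_spec(), "wm"),
                    data = an, se = FALSE)
  cmp <- chi_square_difference(full, nested)
  expect_equal(cmp$delta_df, 4)
  expect_gte(cmp$delta_chisq, 0)
  # two differently-constrained models are not nested in each other
  other <- fit_sem(constrain_variable_paths(fp_sem_spec(), "gm"),
                   data = an, se = FALSE)
  expect_error(chi_square_difference(other, nested), "not nested")
})

test_that("FIML equals complete-data ML and decomposes casewise", {
  an <- cached_analysis(800, 5)
  fml <- fit_sem(fp_sem_spec(), data = an, estimator = "ML",
                 likelihood = "normal", se = FALSE)
  ffi <- fit_sem(fp_sem_spec(), data = an, estimator = "FIML", se = FALSE)
  expect_equal(unname(ffi$theta), unname(fml$theta), tolerance = 1e-6)
  expect_equal(ffi$chisq, fml$chisq, tolerance = 1e-4)
  expect_equal(ffi$loglik, fml$loglik, tolerance = 1e-5)
  # deleting observations cannot decrease the attainable log-likelihood
  sub <- fit_sem(fp_sem_spec(), data = an[1:600, ], estimator = "FIML",
                 se = FALSE)
  expect_gte(sub$loglik, ffi$loglik)
})

test_that("FIML recovers ground truth under missing-at-random data", {
  co <- cached_cohort(4000, 6)
  co_miss <- inject_missingness(co, 0.2, seed = 7)
  an <- prepare_analysis_table(co_miss)
  expect_gt(mean(is.na(an$wmh)), 0.15)
  fit <- fit_sem(fp_sem_spec(), data = an, estimator = "FIML", se = FALSE)
  expect_true(fit$converged)
  std <- fit$standardized
  truth <- c("wmh~cvr" = 0.13, "ef~wm" = 0.34, "ef~gm" = 0.32,
             "wmh~age" = 0.35, "ef=~rt" = 0.49)
  for (lab in names(truth))
    expect_lt(abs(std$std[std$label == lab] - truth[[lab]]), 0.03)
})

test_that("Heywood cases are floored at the variance bound with a warning", {
  S <- matrix(c(1, .7, .7, .7, 1, .2, .7, .2, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  spec <- sem_spec(c("a", "b", "c"), latents = list(f = c("a", "b", "c")))
  w <- capture_warnings(fit2 <- fit_sem(spec, sample_cov = S, n = 500,
                                        se = FALSE))
  expect_true(any(grepl("Heywood", w)))
  expect_gte(min(fit2$theta[grepl("~~", names(fit2$theta))]), 1e-6)
})

test_that("standard errors match the closed-form regression oracle", {
  set.seed(31)
  n <- 500
  x <- rnorm(n); y <- 0.4 * x + rnorm(n, 0, 0.7)
  spec <- sem_spec(c("x", "y"), paths = data.frame(from = "x", to = "y"))
  fit <- fit_sem(spec, data = data.frame(x = x, y = y), se = TRUE)
  lm_se <- summary(lm(y ~ x))$coefficients["x", "Std. Error"]
  se_hat <- fit$ptable$se[fit$ptable$label == "y~x"]
  # asymptotic ML standard error vs small-sample OLS: agree to O(1/n)
  expect_equal(se_hat, lm_se, tolerance = 0.02)
})
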