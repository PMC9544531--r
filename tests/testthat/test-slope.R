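test_that("default weights are normalised inverse variances", {
  p <- make_pairs(beta_x = c(1, 2), beta_y = c(0.5, 1), se_y = c(1, 2))
  w <- default_weights(p)$weight
  expect_equal(w, c(0.8, 0.2))            # 1/1 and 1/4, normalised
  expect_equal(sum(w), 1)

  # scale invariance
  p2 <- p; p2$se_y <- p2$se_y * 7.3
  expect_equal(default_weights(p2)$weight, w)

  # equal scheme
  expect_equal(default_weights(p, scheme = "equal")$weight, c(0.5, 0.5))

  p3 <- p; p3$se_y[1] <- 0
  expect_error(default_weights(p3), "se_y")
})

test_that("IVW slope matches direct arithmetic and ratio limits", {
  # single SNP: Wald ratio, SE undefined
  one <- ivw_slope(make_pairs(2, 1, se_y = 0.1))
  expect_equal(one$b, 0.5)
  expect_true(is.na(one$se_b))

  p <- make_pairs(beta_x = c(1, 2), beta_y = c(0.5, 1.0), se_y = 1)
  est <- ivw_slope(p)
  expect_s3_class(est, "slope_estimate")
  expect_equal(est$b, 1.25 / 2.5)          # equal weights
  expect_equal(est$intercept, 0)
  expect_equal(est$se_b, 0)  # these points lie exactly on the fitted ray

  # joint negation of any SNP leaves the slope unchanged
  p2 <- p; p2$beta_x[2] <- -p2$beta_x[2]; p2$beta_y[2] <- -p2$beta_y[2]
  expect_identical(ivw_slope(p2)$b, est$b)

  expect_error(ivw_slope(make_pairs(c(0, 0), c(1, 1))), "degenerate")
})

test_that("zero-intercept CWLS applies the exact denominator correction", {
  p <- make_pairs(beta_x = c(1, 2), beta_y = c(0.5, 1.0), se_x = 0.1,
                  se_y = 1)
  est <- cwls_zero_intercept(p)
  expect_equal(est$b, 1.25 / (2.5 - 0.01))  # 0.5020080...
  expect_equal(est$diagnostics$denom_uncorrected, 2.5)
  expect_equal(est$diagnostics$denom_corrected, 2.49)
  expect_lte(est$diagnostics$denom_corrected,
             est$diagnostics$denom_uncorrected)

  # no-measurement-error limit: identical to IVW
  p0 <- p; p0$se_x <- 0
  expect_equal(cwls_zero_intercept(p0)$b, ivw_slope(p0)$b)

  # instruments that are pure noise fail loudly
  noisy <- make_pairs(beta_x = c(0.01, -0.02), beta_y = c(0, 0), se_x = 1)
  expect_error(cwls_zero_intercept(noisy), "weak-instrument failure")
})

test_that("free-intercept CWLS matches arithmetic and recovers exact lines", {
  p <- make_pairs(beta_x = c(0, 2), beta_y = c(0, 1), se_x = 0.1, se_y = 1)
  est <- cwls_free_intercept(p)
  expect_equal(est$b, 0.5 / 0.99)                      # 0.5050505...
  expect_equal(est$intercept, 0.5 - est$b * 1.0)       # -0.0050505...

  # noiseless data on a line are recovered exactly
  x <- c(-1, 0, 1, 2)
  line <- make_pairs(x, 0.7 + 1.3 * x, se_x = 0, se_y = 1)
  fit <- cwls_free_intercept(line)
  expect_equal(fit$b, 1.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.7, tolerance = 1e-12)

  expect_error(cwls_free_intercept(make_pairs(1, 1)), "at least 2")
})

test_that("CWLS with se_x = 0 equals a generic weighted least-squares fit", {
  set.seed(31)
  m <- 60
  p <- make_pairs(beta_x = rnorm(m), beta_y = 1 + 0.4 * rnorm(m),
                  se_x = 0, se_y = runif(m, 0.5, 2))
  p$beta_y <- 0.25 + 0.9 * p$beta_x + rnorm(m, 0, 0.3)
  pw <- default_weights(p)
  est <- cwls_free_intercept(pw)
  ref <- lm(beta_y ~ beta_x, data = pw, weights = 1 / se_y^2)
  expect_equal(est$b, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(est$intercept, unname(coef(ref)[1]), tolerance = 1e-10)

  # and the zero-intercept form against lm without intercept
  est0 <- cwls_zero_intercept(pw)
  ref0 <- lm(beta_y ~ 0 + beta_x, data = pw, weights = 1 / se_y^2)
  expect_equal(est0$b, unname(coef(ref0)[1]), tolerance = 1e-10)
})

test_that("sandwich SE matches a generic robust-WLS computation when se_x=0", {
  skip_if_not_installed("sandwich")
  set.seed(77)
  m <- 80
  p <- make_pairs(beta_x = rnorm(m), beta_y = NA, se_x = 0,
                  se_y = runif(m, 0.5, 2))
  p$beta_y <- -0.1 + 0.6 * p$beta_x + rnorm(m, 0, p$se_y / 2)
  pw <- default_weights(p)
  est <- cwls_free_intercept(pw)
  ref <- lm(beta_y ~ beta_x, data = pw, weights = 1 / se_y^2)
  vc <- sandwich::vcovHC(ref, type = "HC0")
  expect_equal(est$se_b, sqrt(vc[2, 2]), tolerance = 1e-10)
})

test_that("duplicating every SNP shrinks the sandwich SE by sqrt(2)", {
  set.seed(5)
  p <- make_pairs(rnorm(40), rnorm(40), se_x = 0.05, se_y = runif(40, 0.5, 2))
  pw <- default_weights(p)
  est <- cwls_zero_intercept(pw)
  dup <- default_weights(dplyr::bind_rows(p, p))
  est2 <- cwls_zero_intercept(dup)
  expect_equal(est2$b, est$b, tolerance = 1e-12)
  expect_equal(est2$se_b, est$se_b / sqrt(2), tolerance = 1e-12)
})

test_that("sandwich SE is calibrated against Monte-Carlo spread", {
  # homoscedastic synthetic data; mean estimated SE within 15% of the
  # empirical SD of the slope over 500 replicates
  set.seed(201)
  m <- 300
  bx <- rnorm(m, 0, 0.05)
  res <- vapply(seq_len(500), function(i) {
    p <- make_pairs(bx, 0.3 * bx + rnorm(m, 0, 0.02), se_x = 0, se_y = 1)
    est <- cwls_zero_intercept(p)
    c(est$b, est$se_b)
  }, numeric(2))
  ratio <- mean(res[2, ]) / sd(res[1, ])
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("zero-intercept estimators are exactly allele-coding invariant", {
  set.seed(9)
  for (i in 1:5) {
    p <- default_weights(make_pairs(rnorm(100), rnorm(100), se_x = 0.05,
                                    se_y = runif(100, 0.5, 2)))
    flip <- sample(c(TRUE, FALSE), 100, replace = TRUE)
    p2 <- p
    p2$beta_x[flip] <- -p2$beta_x[flip]
    p2$beta_y[flip] <- -p2$beta_y[flip]
    expect_identical(cwls_zero_intercept(p2)$b, cwls_zero_intercept(p)$b)
    expect_identical(ivw_slope(p2)$b, ivw_slope(p)$b)
  }
})

test_that("CWLS stays unbiased under weak instruments while IVW attenuates", {
  set.seed(404)
  m <- 4000
  b_true <- -0.4
  tau <- 0.05
  bx_true <- rnorm(m, 0, tau)
  se_x <- rep(tau, m)          # noise variance equals signal variance
  p <- make_pairs(beta_x = bx_true + rnorm(m, 0, se_x),
                  beta_y = b_true * bx_true + rnorm(m, 0, 0.01),
                  se_x = se_x, se_y = 0.01)
  cw <- cwls_zero_intercept(p)
  iv <- ivw_slope(p)
  expect_lt(abs(cw$b - b_true), 3 * cw$se_b)
  # attenuation by the errors-in-variables factor (here 0.5)
  f <- sum(bx_true^2) / (sum(bx_true^2) + sum(se_x^2))
  expect_lt(abs(iv$b - f * b_true), 3 * iv$se_b)
  expect_lt(abs(iv$b), abs(cw$b))
})

test_that("all three estimators converge to the truth as noise vanishes", {
  set.seed(55)
  m <- 20000
  bx <- rnorm(m, 0, 0.05)
  p <- make_pairs(bx, -0.4 * bx + rnorm(m, 0, 0.001), se_x = 0, se_y = 0.001)
  for (f in list(ivw_slope, cwls_zero_intercept, cwls_free_intercept)) {
    est <- f(p)
    expect_lt(abs(est$b + 0.4), 3 * est$se_b + 1e-4)
  }
})

test_that("tidy and glance summarise slope fits in broom style", {
  p <- default_weights(make_pairs(c(0, 2, 1), c(0, 1, 0.6), se_x = 0.1))
  est <- cwls_free_intercept(p)
  td <- tidy(est)
  expect_equal(td$term, c("slope", "intercept"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value")
                  %in% names(td)))
  gl <- glance(est)
  expect_equal(gl$method, "cwls_free")
  expect_equal(gl$n_snps, 3L)
  expect_output(print(est), "cwls_free")
})

test_that("fit_slope dispatches by method name", {
  p <- default_weights(make_pairs(c(1, 2, 3), c(0.5, 1, 1.4), se_x = 0.01))
  expect_equal(fit_slope(p, "ivw")$method, "ivw")
  expect_equal(fit_slope(p, "cwls0")$method, "cwls_zero")
  expect_equal(fit_slope(p, "cwls")$method, "cwls_free")
  expect_error(fit_slope(p, "nope"))
})
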