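test_that("configurations are validated and scaled proportionally", {
  cfg <- sim_config()
  expect_equal(cfg$m_total, 100000L)
  expect_equal(cfg$m_shared, 5000L)
  expect_error(sim_config(h2_x = 0.6), "variance shares")
  expect_error(sim_config(m_total = 1000), "exceed")
  expect_error(sim_config(rho_shared = 1.2), "rho_shared")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")

  small <- scale_genome(cfg, 5)
  expect_equal(small$m_total, 20000L)
  expect_equal(small$m_x_only, 1000L)
  expect_equal(implied_bias_slope(small), implied_bias_slope(cfg))
})

test_that("the analytic bias slope matches the variance partition", {
  expect_identical(implied_bias_slope(sim_config(rho_shared = 0)), -0.4)
  expect_equal(implied_bias_slope(sim_config(rho_shared = 0.45)), -0.5125,
               tolerance = 1e-12)
  expect_equal(implied_bias_slope(sim_config(rho_shared = -0.45)), -0.2875,
               tolerance = 1e-12)
  # no confounding, no shared effects: no collider bias
  expect_identical(
    implied_bias_slope(sim_config(c_conf = 0, v_resid = 0.5, rho_shared = 0)),
    0
  )
})

test_that("true effects carry exact heritability shares and correlations", {
  cfg <- desk_config(rho = 0.45)
  tr <- draw_true_effects(cfg, seed = 4)
  het <- 2 * tr$maf * (1 - tr$maf)
  for (cl in c("x_only", "shared")) {
    expect_equal(sum(het[tr$class == cl] * tr$beta_gx[tr$class == cl]^2),
                 0.25, tolerance = 1e-12)
  }
  for (cl in c("y_only", "shared")) {
    expect_equal(sum(het[tr$class == cl] * tr$beta_gy[tr$class == cl]^2),
                 0.25, tolerance = 1e-12)
  }
  expect_equal(unname(table(tr$class)[c("x_only", "y_only", "shared")]),
               rep(1000L, 3), ignore_attr = TRUE)
  expect_true(all(tr$maf > 0.01 & tr$maf < 0.49))
  expect_true(all(tr$beta_gx[tr$class %in% c("y_only", "null")] == 0))

  # shared-effect correlation close to its target (Fisher-z scale tolerance)
  sh <- tr[tr$class == "shared", ]
  expect_lt(abs(cor(sh$beta_gx, sh$beta_gy) - 0.45), 0.04)

  tr0 <- draw_true_effects(desk_config(rho = 0), seed = 4)
  sh0 <- tr0[tr0$class == "shared", ]
  expect_lt(abs(cor(sh0$beta_gx, sh0$beta_gy)), 3 / sqrt(nrow(sh0)))
})

test_that("summary-mode draws are calibrated to their stated variances", {
  cfg <- desk_config()
  tr <- draw_true_effects(cfg, seed = 9)
  sim <- simulate_summary(cfg, tr, seed = 10)

  # standardised deviations from the generative means are standard normal
  z_x <- (sim$x_stats$beta - tr$beta_gx) / sim$x_stats$se
  b <- implied_bias_slope(cfg)
  z_y <- (sim$y_stats$beta - (tr$beta_gy + b * tr$beta_gx)) / sim$y_stats$se
  expect_lt(abs(sd(z_x) - 1), 0.02)
  expect_lt(abs(sd(z_y) - 1), 0.02)
  expect_lt(abs(mean(z_x)), 3 / sqrt(length(z_x)))

  # reported SE matches the closed form at maf 0.25
  i <- which.min(abs(tr$maf - 0.25))
  expect_equal(sim$x_stats$se[i],
               1 / sqrt(cfg$n * 2 * tr$maf[i] * (1 - tr$maf[i])))

  # a null-on-Y SNP with beta_gx = 0.02 has conditional mean -0.008:
  # 4000 identical SNPs give the Monte-Carlo expectation directly
  tr2 <- tibble::tibble(
    snp_id = paste0("s", 1:4000), maf = 0.25,
    beta_gx = 0.02, beta_gy = 0, class = "x_only"
  )
  sim2 <- simulate_summary(cfg, tr2, seed = 11)
  mc <- sd(sim2$y_stats$beta) / sqrt(4000)
  expect_lt(abs(mean(sim2$y_stats$beta) - (-0.008)), 3 * mc)
})

test_that("summary mode is deterministic given seed and config", {
  cfg <- sim_config(m_total = 2000, m_x_only = 100, m_y_only = 100,
                    m_shared = 100, n = 5000)
  s1 <- simulate_summary(cfg, seed = 77)
  s2 <- simulate_summary(cfg, seed = 77)
  expect_identical(s1$x_stats, s2$x_stats)
  expect_identical(s1$y_stats, s2$y_stats)
  s3 <- simulate_summary(cfg, seed = 78)
  expect_false(identical(s3$x_stats$beta, s1$x_stats$beta))
})

test_that("individual-level traits realise the variance partition", {
  cfg <- sim_config(m_total = 500, m_x_only = 80, m_y_only = 80,
                    m_shared = 80, n = 20000)
  sim <- simulate_individual(cfg, seed = 3)
  expect_lt(abs(var(sim$x) - 1), 0.02)
  expect_lt(abs(var(sim$y) - 1), 0.02)

  # with no confounding and no shared SNPs there is no collider path
  cfg0 <- sim_config(m_total = 400, m_x_only = 80, m_y_only = 80,
                     m_shared = 0, c_conf = 0, v_resid = 0.5, n = 8000)
  sim0 <- simulate_individual(cfg0, seed = 5)
  pr0 <- sim_pairs(sim0)
  xo <- pr0[pr0$class == "x_only", ]
  expect_lt(abs(mean(xo$beta_y)), 3 * sd(xo$beta_y) / sqrt(nrow(xo)))

  expect_error(simulate_individual(sim_config(), seed = 1), "memory budget")
})

test_that("individual-mode conditional effects recover the analytic slope", {
  cfg <- sim_config(m_total = 2000, m_x_only = 200, m_y_only = 200,
                    m_shared = 200, n = 10000)
  sim <- simulate_individual(cfg, seed = 21)
  pr <- sim_pairs(sim)
  xo <- pr$class == "x_only"
  fit <- lm(pr$beta_y[xo] ~ sim$truth$beta_gx[sim$truth$class == "x_only"])
  slope_se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(coef(fit)[[2]] - implied_bias_slope(cfg)), 3 * slope_se)
})

test_that("summary and individual modes agree in distribution", {
  cfg <- sim_config(m_total = 2000, m_x_only = 200, m_y_only = 200,
                    m_shared = 200, n = 10000)
  sim_i <- simulate_individual(cfg, seed = 21)
  sim_s <- simulate_summary(cfg, truth = sim_i$truth, seed = 22)
  b <- implied_bias_slope(cfg)
  mu <- sim_i$truth$beta_gy + b * sim_i$truth$beta_gx
  z_i <- (sim_i$y_stats$beta - mu) / sim_i$y_stats$se
  z_s <- (sim_s$y_stats$beta - mu) / sim_s$y_stats$se
  expect_gt(suppressWarnings(ks.test(z_i, z_s)$p.value), 0.01)
})

test_that("sim_pairs attaches truth classes to harmonised pairs", {
  cfg <- sim_config(m_total = 300, m_x_only = 30, m_y_only = 30,
                    m_shared = 30, n = 2000)
  sim <- simulate_summary(cfg, seed = 2)
  pr <- sim_pairs(sim)
  expect_equal(nrow(pr), 300L)
  expect_true(all(c("class", "beta_gy_true") %in% names(pr)))
  expect_equal(sum(pr$class == "shared"), 30L)
})
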