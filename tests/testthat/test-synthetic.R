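test_that("simulation is reproducible from (config, seed)", {
  cfg <- preset_community(seed = 5)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$panel$catch, s2$panel$catch)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_community(cfg, seed = 6)
  expect_false(identical(s1$panel$catch, s3$panel$catch))
})

test_that("effort layer: Poisson around a log random walk, missing flags", {
  cfg <- preset_community(seed = 2, lambda1 = 100, sigma_lambda = 0,
                          missing_years = c(1970L, 1971L))
  eff <- simulate_effort(cfg)
  expect_equal(unname(eff$lambda), rep(100, 57))
  # Poisson mean check at sigma_lambda = 0 (3 x sqrt(lambda/n) slack)
  expect_lt(abs(mean(eff$z_true) - 100), 3 * sqrt(100 / 57))
  expect_identical(sum(eff$effort$missing), 2L)
  expect_true(all(is.na(eff$effort$n_fishers[eff$effort$missing])))
  expect_false(anyNA(eff$z_true))
})

test_that("temperature layer: trend plus noise", {
  cfg0 <- preset_community(seed = 4, temp_base = 14.5, temp_trend = 0,
                           temp_sd = 0)
  expect_equal(simulate_temperature(cfg0)$temp_c, rep(14.5, 57))
  cfg1 <- preset_community(seed = 4, temp_trend = 0.02, temp_sd = 0)
  tt <- simulate_temperature(cfg1)$temp_c
  expect_equal(tt[57] - tt[1], 0.02 * 56)
  # Monte-Carlo: per-year SD of replicate series matches the noise SD
  cfg2 <- preset_community(seed = 4, temp_trend = 0, temp_sd = 0.5)
  reps <- vapply(1:400, function(r) {
    simulate_temperature(cfg2, seed = r)$temp_c[10]
  }, numeric(1))
  expect_lt(abs(sd(reps) - 0.5), 0.06)
})

test_that("noise-free limit reduces to piecewise-exponential CPUE", {
  cfg <- preset_community(seed = 9, sigma_x = 0, sigma_y = 0, logx1_sd = 0,
                          gamma = 0, temp_sd = 0, missing_years = integer())
  sim <- simulate_community(cfg)
  tx <- "Carassius spp."
  lx <- sim$truth$logx[tx, ]
  inc <- diff(lx)
  p <- assign_periods(cfg$years, cfg$schemes[[tx]])
  b <- cfg$beta[tx, ]
  # increment into year t carries the period coefficient of year t-1
  expected <- c(b[["beta1"]], b[["beta1"]] + b[["beta2"]],
                b[["beta1"]] + b[["beta3"]])[p[-57]]
  expect_equal(unname(inc), unname(expected))
  # log catch = log CPUE + log effort exactly when sigma_y = 0
  z <- sim$truth$z
  expect_equal(log(sim$panel$catch[tx, ]), lx + log(z))
  # example arithmetic: beta1 = 0.1, beta2 = -0.3 -> period-2 increment -0.2
  cfg2 <- preset_community(seed = 9, sigma_x = 0, sigma_y = 0, logx1_sd = 0,
                           gamma = 0, temp_sd = 0,
                           beta = matrix(c(0.1, -0.3, -0.2), 8, 3,
                                         byrow = TRUE))
  sim2 <- simulate_community(cfg2)
  expect_equal(unname(diff(sim2$truth$logx[1, ])[11]), -0.2) # 1977, in P2
})

test_that("process-noise moments match sigma_x (Monte Carlo)", {
  tx <- "Zacco platypus"
  resid <- vapply(1:300, function(r) {
    cfg <- sim_config(taxa = tx, schemes = default_schemes(tx),
                      beta = matrix(c(0.05, -0.1, -0.2), 1), gamma = -0.05,
                      sigma_x = 0.2, sigma_y = 0.3, seed = r)
    sim <- simulate_community(cfg)
    # residual of one fixed transition (year 20 -> 21) net of drift
    sim$truth$logx[1, 21] - sim$truth$logx[1, 20] - sim$truth$drift[1, 20]
  }, numeric(1))
  v <- var(resid)
  se <- 0.04 * sqrt(2 / 299)
  expect_lt(abs(v - 0.04), 3 * se)
})

test_that("zero injection produces floored entries downstream", {
  cfg <- preset_community(
    seed = 12, inject_zero_years = list("Squalidus spp." = c(2001L, 2002L)))
  sim <- simulate_community(cfg)
  expect_identical(sum(sim$panel$catch == 0), 2L)
  lc <- preprocess_catch(sim$panel$catch)
  expect_identical(sum(lc == log(50)), 2L)
})

test_that("generated panels round-trip through the CSV writer/reader", {
  cfg <- preset_community(seed = 8)
  sim <- simulate_community(cfg)
  d <- withr::local_tempdir()
  write_panel(sim$panel, d)
  back <- read_panel(d, quiet = TRUE)
  expect_equal(back$catch, sim$panel$catch, tolerance = 1e-12)
  expect_identical(back$effort$n_fishers, sim$panel$effort$n_fishers)
  expect_identical(back$effort$missing, sim$panel$effort$missing)
  expect_equal(back$temperature$temp_c, sim$panel$temperature$temp_c,
               tolerance = 1e-12)
  expect_identical(names(back$schemes), names(sim$panel$schemes))
  expect_equal(back$schemes[["Gnathopogon caerulescens"]]$boundaries,
               sim$panel$schemes[["Gnathopogon caerulescens"]]$boundaries)
})

test_that("config validation rejects impossible worlds", {
  expect_error(preset_community(sigma_x = -1), "SD")
  expect_error(preset_community(lambda1 = 0), "lambda1")
  expect_error(preset_community(missing_years = 1950L), "missing_years")
  expect_error(preset_community(beta4 = c("Zacco platypus" = 0.1)),
               "restoration")
})
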