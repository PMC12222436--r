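small_world <- function(seed = 17, missing_years = c(1980L, 1995L)) {
  taxa <- c("Zacco platypus", "Gnathopogon caerulescens")
  cfg <- preset_community(seed = seed, taxa = taxa,
                          schemes = default_schemes(taxa),
                          beta = matrix(c(0.05, -0.05, -0.25,
                                          0.05, -0.02, -0.3), 2, 3,
                                        byrow = TRUE),
                          beta4 = c("Gnathopogon caerulescens" = 0.25),
                          gamma = -0.05, missing_years = missing_years)
  sim <- simulate_community(cfg)
  list(cfg = cfg, sim = sim,
       prep = prepare_data(sim$panel, cfg$schemes))
}

test_that("fits are reproducible from the seed", {
  w <- small_world()
  f1 <- fit_ssm(w$prep, n_chains = 2, n_iter = 200, warmup = 50, seed = 5,
                monitor = c("beta", "hyper"))
  f2 <- fit_ssm(w$prep, n_chains = 2, n_iter = 200, warmup = 50, seed = 5,
                monitor = c("beta", "hyper"))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ssm(w$prep, n_chains = 2, n_iter = 200, warmup = 50, seed = 6,
                monitor = c("beta", "hyper"))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("state posterior means match the Kalman smoother oracle", {
  # linear-Gaussian reduction: one taxon, known variances and
  # coefficients, effort fully observed -> FFBS draws are exact
  tx <- "Opsariichthys uncirostris"
  cfg <- sim_config(taxa = tx, schemes = default_schemes(tx),
                    beta = matrix(c(0.05, -0.25, -0.2), 1), gamma = -0.05,
                    sigma_x = 0.15, sigma_y = 0.3,
                    missing_years = integer(), seed = 101)
  sim <- simulate_community(cfg)
  prep <- prepare_data(sim$panel, cfg$schemes)
  fit <- fit_ssm(prep, n_chains = 2, n_iter = 2500, warmup = 500, seed = 202,
                 monitor = "states",
                 fix = list(beta = cfg$beta, gamma = cfg$gamma,
                            sigma_y = 0.3, sigma_x = 0.15))
  d <- extract_draws(fit, "^logx\\[")
  yr <- as.integer(sub(".*,(\\d+)\\]$", "\\1", colnames(d)))
  d <- d[, order(yr)]
  z <- sim$panel$effort$n_fishers
  w <- log(sim$panel$catch[1, ]) - log(z)
  n_t <- 57L
  ind <- build_indicators(cfg$schemes, cfg$years)
  anom <- compute_anomaly(sim$panel$temperature, cfg$schemes, cfg$years)
  drift <- 0.05 - 0.25 * ind[1, -n_t, "P2"] - 0.2 * ind[1, -n_t, "P3"] -
    0.05 * anom[1, -n_t]
  ks <- kalman_smoother(w, drift, 0.3^2, 0.15^2, w[1],
                        default_priors()$init_sd^2)
  zscore <- (colMeans(d) - ks$mean) / (apply(d, 2, sd) / sqrt(nrow(d)))
  # 4-SE bound here (57 simultaneous comparisons); the acceptance suite
  # applies the 3-SE criterion at its own scale
  expect_lt(max(abs(zscore)), 4)
  expect_lt(mean(abs(colMeans(d) - ks$mean)), 0.01)
})

test_that("latent effort counts are positive integers at missing years", {
  w <- small_world()
  fit <- fit_ssm(w$prep, n_chains = 2, n_iter = 400, warmup = 100, seed = 9,
                 monitor = "effort")
  zd <- extract_draws(fit, "^z\\[")
  expect_identical(colnames(zd), paste0("z[", c(1980L, 1995L), "]"))
  expect_true(all(zd >= 1))
  expect_true(all(zd == round(zd)))
})

test_that("supplying the true effort tightens community-mean posteriors", {
  w <- small_world(seed = 29, missing_years = c(1975L, 1985L, 1995L, 2005L,
                                                2010L, 2015L))
  fit_miss <- fit_ssm(w$prep, n_chains = 2, n_iter = 2000, warmup = 500,
                      seed = 13, monitor = "hyper")
  # same panel with the generator's true effort restored everywhere
  panel_full <- w$sim$panel
  panel_full$effort$n_fishers <- as.integer(w$sim$truth$z)
  panel_full$effort$missing <- rep(FALSE, 57)
  prep_full <- prepare_data(panel_full, w$cfg$schemes)
  fit_full <- fit_ssm(prep_full, n_chains = 2, n_iter = 2000, warmup = 500,
                      seed = 13, monitor = "hyper")
  sd_miss <- mean(apply(extract_draws(fit_miss, "^mu\\["), 2, sd))
  sd_full <- mean(apply(extract_draws(fit_full, "^mu\\["), 2, sd))
  expect_lte(sd_full, sd_miss)
})

test_that("monitor subsets and metadata behave", {
  w <- small_world()
  fit <- fit_ssm(w$prep, n_chains = 2, n_iter = 200, warmup = 100, seed = 2,
                 monitor = "beta")
  qn <- dimnames(fit$draws)[[3]]
  expect_true(all(grepl("^beta", qn)))
  expect_true("beta4[Gnathopogon caerulescens]" %in% qn)
  expect_false("beta4[Zacco platypus]" %in% qn)
  expect_identical(length(fit$rhat), length(qn))
  expect_error(extract_draws(fit, "^mu\\["), "no monitored")
  expect_error(fit_ssm(w$prep, fix = list(beta = w$cfg$beta)), "together")
  rel <- fit_ssm(w$prep, n_chains = 2, n_iter = 200, warmup = 100, seed = 2,
                 monitor = "effort", effort_mode = "relaxed")
  expect_identical(rel$config$effort_mode, "relaxed")
  zd <- extract_draws(rel, "^z\\[")
  expect_true(all(zd >= 1))
})
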