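test_that("preprocess_catch floors zeros at the record minimum", {
  expect_equal(preprocess_catch(0), log(50))
  expect_equal(preprocess_catch(1000), log(1000))
  expect_equal(preprocess_catch(c(0, 3, 0, 7), floor = 50),
               log(c(50, 3, 50, 7)))
  x <- matrix(c(0, 10, 0, 0, 5, 2), 2, 3)
  expect_identical(sum(preprocess_catch(x) == log(50)), 3L)
  expect_error(preprocess_catch(-5), ">= 0")
  expect_error(preprocess_catch(10, floor = 0), "floor")
})

test_that("growth_mean composes period coefficients", {
  b <- c(beta1 = 0.1, beta2 = -0.3, beta3 = -0.15)
  expect_equal(growth_mean(b, c(P2 = 0, P3 = 0, P4 = 0)), 0.1)
  expect_equal(growth_mean(b, c(P2 = 1, P3 = 0, P4 = 0)), -0.2)
  expect_equal(growth_mean(b, c(P2 = 0, P3 = 1, P4 = 0)), -0.05)
  expect_equal(growth_mean(c(beta1 = 0.05, beta2 = 0, beta3 = 0,
                             beta4 = 0.2), c(0, 0, 1)), 0.25)
  expect_error(growth_mean(b, c(P2 = 0, P3 = 0, P4 = 1)), "restoration")
  expect_error(growth_mean(b, c(P2 = 1, P3 = 1, P4 = 0)), "at most one")
})

test_that("climate_term is the anomaly product", {
  expect_equal(climate_term(-0.1, 2), -0.2)
  expect_equal(climate_term(0.7, 0), 0)
  expect_equal(climate_term(0, c(-3, 5)), c(0, 0))
  expect_error(climate_term(0.1, NaN), "finite")
})

test_that("log_joint matches a from-scratch scalar-density oracle", {
  w <- tiny_world()
  data <- prepare_data(w$panel, w$schemes)
  params <- tiny_params()
  states <- tiny_states()
  priors <- default_priors()
  got <- log_joint(params, states, data, priors)
  oracle <- log_joint_oracle(w, params, states, priors, z = c(120, 103, 95))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("log_joint likelihood is additive and taxon-exchangeable", {
  w <- tiny_world(missing_year = NA)
  data <- prepare_data(w$panel, w$schemes)
  params <- tiny_params()
  states <- tiny_states()
  states$z_missing <- NULL
  parts <- log_joint(params, states, data, parts = TRUE)
  # per-taxon observation/process terms sum over taxa: drop taxon B by
  # computing the single-taxon world and differencing
  wA <- tiny_world(missing_year = NA)
  panelA <- fishery_panel(wA$panel$catch[1, , drop = FALSE],
                          wA$panel$effort, wA$panel$temperature,
                          schemes = wA$schemes["A"])
  dataA <- prepare_data(panelA, wA$schemes["A"])
  paramsA <- params
  paramsA$beta <- params$beta[1, , drop = FALSE]
  paramsA$gamma <- params$gamma[1]
  paramsA$sigma_y <- params$sigma_y[1]
  paramsA$sigma_x <- params$sigma_x[1]
  paramsA$beta4 <- numeric()
  statesA <- states
  statesA$logx <- states$logx[1, , drop = FALSE]
  partsA <- log_joint(paramsA, statesA, dataA, parts = TRUE)
  panelB <- fishery_panel(wA$panel$catch[2, , drop = FALSE],
                          wA$panel$effort, wA$panel$temperature,
                          schemes = wA$schemes["B"])
  dataB <- prepare_data(panelB, wA$schemes["B"])
  paramsB <- params
  paramsB$beta <- params$beta[2, , drop = FALSE]
  paramsB$gamma <- params$gamma[2]
  paramsB$sigma_y <- params$sigma_y[2]
  paramsB$sigma_x <- params$sigma_x[2]
  statesB <- states
  statesB$logx <- states$logx[2, , drop = FALSE]
  partsB <- log_joint(paramsB, statesB, dataB, parts = TRUE)
  for (term in c("observation", "process")) {
    expect_equal(parts[[term]], partsA[[term]] + partsB[[term]],
                 tolerance = 1e-12)
  }
  # shared effort layers counted once
  expect_equal(parts[["effort_obs"]], partsA[["effort_obs"]])
  expect_equal(parts[["effort_process"]], partsA[["effort_process"]])
  # permuting taxa leaves the total unchanged
  perm_panel <- fishery_panel(wA$panel$catch[2:1, ], wA$panel$effort,
                              wA$panel$temperature,
                              schemes = wA$schemes[2:1])
  perm_data <- prepare_data(perm_panel, wA$schemes[2:1])
  perm_params <- params
  perm_params$beta <- params$beta[2:1, ]
  perm_params$gamma <- params$gamma[2:1]
  perm_params$sigma_y <- params$sigma_y[2:1]
  perm_params$sigma_x <- params$sigma_x[2:1]
  perm_states <- states
  perm_states$logx <- states$logx[2:1, ]
  expect_equal(log_joint(perm_params, perm_states, perm_data),
               log_joint(params, states, data), tolerance = 1e-12)
})

test_that("observation terms shift by -log 2 when sigma_y doubles at the mean", {
  w <- tiny_world(missing_year = NA)
  data <- prepare_data(w$panel, w$schemes)
  params <- tiny_params()
  states <- tiny_states()
  states$z_missing <- NULL
  # place every observation exactly at its mean
  data$log_catch <- states$logx +
    matrix(log(c(120, 101, 95)), 2, 3, byrow = TRUE)
  p1 <- log_joint(params, states, data, parts = TRUE)
  params2 <- params
  params2$sigma_y <- 2 * params$sigma_y
  p2 <- log_joint(params2, states, data, parts = TRUE)
  expect_equal(p1[["observation"]] - p2[["observation"]], 6 * log(2),
               tolerance = 1e-12)
})

test_that("log_joint validates standard deviations at the boundary", {
  w <- tiny_world(missing_year = NA)
  data <- prepare_data(w$panel, w$schemes)
  params <- tiny_params()
  states <- tiny_states()
  states$z_missing <- NULL
  params$sigma_x[1] <- 0
  expect_error(log_joint(params, states, data), "> 0")
})
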