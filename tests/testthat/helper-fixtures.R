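# tiny 2-taxon, 3-year world used by the log_joint oracle tests:
# taxon A has periods 1/2/3, taxon B has periods 1/2/4 (restoration),
# effort missing in the middle year
tiny_world <- function(missing_year = 1967L) {
  schemes <- list(
    A = period_scheme("A", data.frame(period = 1:3,
                                      first_year = 1966:1968,
                                      last_year = 1966:1968)),
    B = period_scheme("B", data.frame(period = c(1L, 2L, 4L),
                                      first_year = 1966:1968,
                                      last_year = 1966:1968)))
  catch <- matrix(c(1200, 900, 1500, 2000, 1800, 2200), 2, 3, byrow = TRUE,
                  dimnames = list(c("A", "B"), 1966:1968))
  effort <- data.frame(year = 1966:1968, n_fishers = c(120L, NA, 95L))
  if (is.na(missing_year)) effort$n_fishers[2L] <- 101L
  temperature <- data.frame(year = 1966:1968, temp_c = c(14.1, 14.6, 15.0))
  panel <- fishery_panel(catch, effort, temperature, schemes = schemes)
  list(panel = panel, schemes = schemes)
}

tiny_params <- function() {
  list(beta = matrix(c(0.05, -0.2, -0.1, 0.02, -0.15, -0.25), 2, 3,
                     byrow = TRUE,
                     dimnames = list(c("A", "B"),
                                     c("beta1", "beta2", "beta3"))),
       beta4 = c(B = 0.2),
       gamma = c(A = -0.05, B = 0.03),
       sigma_y = c(0.3, 0.25), sigma_x = c(0.15, 0.2),
       sigma_lambda = 0.05,
       mu = c(0.02, -0.15, -0.2, -0.01),
       Sigma = diag(c(0.04, 0.05, 0.05, 0.02)) + 0.01)
}

tiny_states <- function() {
  list(logx = matrix(c(2.1, 2.0, 2.2, 2.9, 2.8, 3.0), 2, 3, byrow = TRUE,
                     dimnames = list(c("A", "B"), 1966:1968)),
       loglambda = c(log(110), log(105), log(100)),
       z_missing = c("1967" = 103L))
}

# independent multivariate normal log-density (solve-based, no cholesky)
dmvnorm_oracle <- function(x, mean, Sigma) {
  p <- length(x)
  as.numeric(-0.5 * p * log(2 * pi) - 0.5 * determinant(Sigma)$modulus -
               0.5 * t(x - mean) %*% solve(Sigma) %*% (x - mean))
}

# independent inverse-Wishart log-density (textbook formula)
dinvwishart_oracle <- function(W, df, S) {
  p <- nrow(W)
  lgamma_p <- 0.25 * p * (p - 1) * log(pi) +
    sum(lgamma(0.5 * (df + 1 - seq_len(p))))
  as.numeric(0.5 * df * determinant(S)$modulus -
               0.5 * (df + p + 1) * determinant(W)$modulus -
               0.5 * sum(diag(S %*% solve(W))) -
               0.5 * df * p * log(2) - lgamma_p)
}

# independent type-7 empirical quantile (order statistics + interpolation)
quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# quick reduced fit of the standard community preset, shared across tests
demo_fit_cache <- new.env(parent = emptyenv())
demo_fit <- function() {
  if (is.null(demo_fit_cache$fit)) {
    cfg <- preset_community(seed = 7)
    sim <- simulate_community(cfg)
    prep <- prepare_data(sim$panel, cfg$schemes)
    demo_fit_cache$cfg <- cfg
    demo_fit_cache$sim <- sim
    demo_fit_cache$fit <- fit_ssm(prep, n_chains = 4, n_iter = 5000,
                                  warmup = 1000, thin = 4, seed = 11)
  }
  list(cfg = demo_fit_cache$cfg, sim = demo_fit_cache$sim,
       fit = demo_fit_cache$fit)
}

# hand-built ssm_draws object for summary-stage unit tests
fake_fit <- function(qmat, taxa, restoration = NULL, n_chains = 2L,
                     years = integer(), missing_years = integer()) {
  n <- nrow(qmat)
  stopifnot(n %% n_chains == 0)
  if (is.null(restoration)) {
    restoration <- stats::setNames(rep(FALSE, length(taxa)), taxa)
  }
  draws <- array(NA_real_, c(n / n_chains, n_chains, ncol(qmat)),
                 dimnames = list(NULL, paste0("chain", seq_len(n_chains)),
                                 colnames(qmat)))
  for (ch in seq_len(n_chains)) {
    draws[, ch, ] <- qmat[seq.int(ch, n, by = n_chains), ]
  }
  structure(list(draws = draws, rhat = rep(NA_real_, ncol(qmat)),
                 converged = NA,
                 config = list(n_chains = n_chains, monitor = "manual"),
                 taxa = taxa, years = years, restoration = restoration,
                 missing_years = missing_years),
            class = "ssm_draws")
}

# full from-scratch oracle for the tiny 2-taxon, 3-year world: every term
# accumulated with scalar stats::d* calls, independent of log_joint()
log_joint_oracle <- function(world, params, states, priors, z) {
  L <- log(world$panel$catch)
  obs <- 0
  for (i in 1:2) for (t in 1:3) {
    obs <- obs + dnorm(L[i, t], states$logx[i, t] + log(z[t]),
                       params$sigma_y[i], log = TRUE)
  }
  ind <- build_indicators(world$schemes, 1966:1968)
  an <- compute_anomaly(world$panel$temperature, world$schemes, 1966:1968)
  proc <- 0
  for (i in 1:2) for (t in 2:3) {
    b4 <- if (i == 2) params$beta4[["B"]] else 0
    R <- params$beta[i, 1] + params$beta[i, 2] * ind[i, t - 1, "P2"] +
      params$beta[i, 3] * ind[i, t - 1, "P3"] + b4 * ind[i, t - 1, "P4"]
    S <- params$gamma[i] * an[i, t - 1]
    proc <- proc + dnorm(states$logx[i, t], states$logx[i, t - 1] + R + S,
                         params$sigma_x[i], log = TRUE)
  }
  lam <- exp(states$loglambda)
  eff_obs <- sum(dpois(z, lam, log = TRUE))
  if (any(world$panel$effort$missing)) {
    eff_obs <- eff_obs - sum(log(1 - exp(-lam[world$panel$effort$missing])))
  }
  eff_proc <- sum(dnorm(states$loglambda[2:3], states$loglambda[1:2],
                        params$sigma_lambda, log = TRUE))
  z1 <- world$panel$effort$n_fishers[!world$panel$effort$missing][1]
  prior <- dmvnorm_oracle(c(params$beta[1, ], params$gamma[1]), params$mu,
                          params$Sigma) +
    dmvnorm_oracle(c(params$beta[2, ], params$gamma[2]), params$mu,
                   params$Sigma) +
    dnorm(params$beta4[["B"]], 0, priors$beta4_sd, log = TRUE) +
    sum(dnorm(states$logx[, 1], L[, 1] - log(z1), priors$init_sd,
              log = TRUE)) +
    dnorm(states$loglambda[1], log(z1), priors$init_sd, log = TRUE)
  hyper <- sum(dnorm(params$mu, 0, priors$mu_sd, log = TRUE)) +
    dinvwishart_oracle(params$Sigma, priors$Sigma_df, priors$Sigma_scale) -
    5 * log(priors$sd_max)
  obs + proc + eff_obs + eff_proc + prior + hyper
}
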