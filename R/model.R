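#' Floor zero catches and take logs
#'
#' The observation layer is lognormal and cannot absorb exact zeros, so
#' zero catches are replaced by the smallest value the record can register
#' (50 g by default) before taking natural logs. Nonzero entries are
#' unchanged before logging.
#'
#' @param catch numeric vector/matrix of catches in grams (>= 0).
#' @param floor replacement value for zeros, in grams.
#' @return log-catch of the same shape.
#' @export
preprocess_catch <- function(catch, floor = 50) {
  if (any(catch < 0, na.rm = TRUE)) stop("catch must be >= 0")
  if (floor <= 0) stop("floor must be > 0")
  catch[catch == 0] <- floor
  log(catch)
}

#' Period-specific mean log growth rate
#'
#' `R = beta1 + beta2 P2 + beta3 P3 (+ beta4 P4)`, evaluated with the
#' indicators of the year preceding the transition. The baseline (all
#' indicators zero) is period 1 with growth `beta1`.
#'
#' @param beta named numeric with `beta1`, `beta2`, `beta3` and optionally
#'   `beta4`.
#' @param indicators numeric vector `c(P2, P3, P4)` (a single row) or a
#'   matrix with those columns.
#' @return Mean log growth rate(s).
#' @export
growth_mean <- function(beta, indicators) {
  ind <- if (is.matrix(indicators)) indicators else
    matrix(indicators, nrow = 1L,
           dimnames = list(NULL, c("P2", "P3", "P4")[seq_along(indicators)]))
  if (ncol(ind) == 2L) ind <- cbind(ind, P4 = 0)
  if (any(rowSums(ind) > 1L)) stop("at most one period indicator may be 1")
  b4 <- if ("beta4" %in% names(beta)) beta[["beta4"]] else NA_real_
  if (any(ind[, 3L] > 0) && is.na(b4)) {
    stop("period-4 indicator set but taxon has no beta4 (not a restoration taxon)")
  }
  if (is.na(b4)) b4 <- 0
  unname(beta[["beta1"]] + beta[["beta2"]] * ind[, 1L] +
           beta[["beta3"]] * ind[, 2L] + b4 * ind[, 3L])
}

#' Temperature-anomaly contribution to log growth
#'
#' `S = gamma * T`, with the anomaly of the preceding year.
#'
#' @param gamma anomaly coefficient (per degree C).
#' @param anomaly anomaly value(s), degrees C.
#' @return Contribution(s) to the log growth rate.
#' @export
climate_term <- function(gamma, anomaly) {
  if (any(!is.finite(anomaly))) stop("anomaly must be finite")
  gamma * anomaly
}

#' Assemble model-ready data from a panel
#'
#' Floors and logs the catch, extracts the observed effort and its missing
#' mask, and precomputes indicator and anomaly covariates under the given
#' schemes.
#'
#' @param panel a [fishery_panel()].
#' @param schemes named list of [period_scheme()], one per panel taxon.
#' @param floor zero-catch replacement (grams).
#' @return Object of class `prepared_data`.
#' @export
prepare_data <- function(panel, schemes = panel$schemes, floor = 50) {
  stopifnot(inherits(panel, "fishery_panel"))
  if (is.null(schemes)) stop("no period schemes supplied or attached")
  if (!all(panel$taxa %in% names(schemes))) {
    stop("schemes missing for taxa: ",
         paste(setdiff(panel$taxa, names(schemes)), collapse = ", "))
  }
  schemes <- schemes[panel$taxa]
  structure(list(
    log_catch = preprocess_catch(panel$catch, floor),
    effort = panel$effort$n_fishers,
    effort_missing = panel$effort$missing,
    indicators = build_indicators(schemes, panel$years),
    anomaly = compute_anomaly(panel$temperature, schemes, panel$years),
    taxa = panel$taxa, years = panel$years,
    restoration = vapply(schemes, function(s) s$has_period4, logical(1L)),
    schemes = schemes, floor = floor),
    class = "prepared_data")
}

#' @export
print.prepared_data <- function(x, ...) {
  cat("Prepared data:", length(x$taxa), "taxa x", length(x$years),
      "years;", sum(x$effort_missing), "missing effort year(s)\n")
  invisible(x)
}

#' Default prior settings
#'
#' Vague-but-proper priors: Normal(0, `mu_sd`^2) on each community
#' hyper-mean component; inverse-Wishart(`Sigma_df`, `Sigma_scale`) on the
#' community covariance; Normal(0, `beta4_sd`^2) on restoration effects
#' (outside the community prior); uniform(0, `sd_max`] on every standard
#' deviation; Normal(empirical proxy, `init_sd`^2) on initial states.
#'
#' @param mu_sd SD of the hyper-mean prior.
#' @param Sigma_df,Sigma_scale inverse-Wishart degrees of freedom and scale
#'   matrix (df = p + 2 makes the prior mean equal `Sigma_scale`).
#' @param beta4_sd SD of the restoration-effect prior.
#' @param sd_max upper bound of the uniform prior on SDs.
#' @param init_sd SD of the initial-state priors.
#' @return List of class `ssm_priors`.
#' @export
default_priors <- function(mu_sd = 10, Sigma_df = 6,
                           Sigma_scale = diag(0.05, 4),
                           beta4_sd = 10, sd_max = 100, init_sd = 10) {
  stopifnot(Sigma_df > 3, nrow(Sigma_scale) == 4, sd_max > 0)
  structure(list(mu_sd = mu_sd, Sigma_df = Sigma_df,
                 Sigma_scale = Sigma_scale, beta4_sd = beta4_sd,
                 sd_max = sd_max, init_sd = init_sd),
            class = "ssm_priors")
}

# empirical initial-state anchors shared by log_joint and the sampler:
# log x_{i,1} centred on first-year log catch minus log of the first
# observed effort; log lambda_1 centred on log of the first observed effort.
init_anchors <- function(data) {
  z1 <- data$effort[!data$effort_missing][1L]
  list(logx1 = data$log_catch[, 1L] - log(z1), loglambda1 = log(z1))
}

mvnorm_logpdf <- function(x, mean, Sigma) {
  p <- length(mean)
  ch <- chol(Sigma)
  dev <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(dev^2)
}

invwishart_logpdf <- function(W, df, S) {
  p <- nrow(W)
  chS <- chol(S); chW <- chol(W)
  ldS <- 2 * sum(log(diag(chS))); ldW <- 2 * sum(log(diag(chW)))
  tr <- sum(diag(S %*% chol2inv(chW)))
  0.5 * df * ldS - 0.5 * (df + p + 1) * ldW - 0.5 * tr -
    0.5 * df * p * log(2) - 0.25 * p * (p - 1) * log(pi) -
    sum(lgamma(0.5 * (df + 1 - seq_len(p))))
}

#' Joint log-density of the state-space model
#'
#' Sums the observation, process, effort-observation, effort-process,
#' hierarchical-prior and hyperprior layers. Latent effort counts at
#' missing years are zero-truncated Poisson. Additive over taxa and years.
#'
#' @param params list with `beta` (matrix `[taxon, beta1..beta3]`), `beta4`
#'   (named numeric for restoration taxa), `gamma`, `sigma_y`, `sigma_x`
#'   (numeric per taxon), `sigma_lambda`, `mu` (length 4), `Sigma` (4 x 4).
#' @param states list with `logx` (matrix `[taxon, year]`), `loglambda`
#'   (numeric per year), `z_missing` (named integer per missing year).
#' @param data a [prepare_data()] object.
#' @param priors an [default_priors()] object.
#' @param parts return the named components instead of the total.
#' @return Scalar log-density, or a named numeric of components.
#' @export
log_joint <- function(params, states, data, priors = default_priors(),
                      parts = FALSE) {
  stopifnot(inherits(data, "prepared_data"))
  sds <- c(params$sigma_y, params$sigma_x, params$sigma_lambda)
  if (any(sds <= 0)) stop("all standard deviations must be > 0")
  if (any(sds > priors$sd_max)) stop("standard deviation above prior bound")
  n_i <- length(data$taxa); n_t <- length(data$years)
  z <- data$effort
  if (any(data$effort_missing)) {
    zm <- states$z_missing[as.character(data$years[data$effort_missing])]
    if (anyNA(zm) || any(zm < 1)) stop("z_missing must cover missing years with counts >= 1")
    z[data$effort_missing] <- zm
  }
  logz <- log(z)
  obs <- sum(stats::dnorm(data$log_catch,
                          states$logx + matrix(logz, n_i, n_t, byrow = TRUE),
                          params$sigma_y, log = TRUE))
  proc <- 0
  for (i in seq_len(n_i)) {
    tx <- data$taxa[i]
    beta_i <- c(beta1 = params$beta[i, 1L], beta2 = params$beta[i, 2L],
                beta3 = params$beta[i, 3L])
    if (data$restoration[[tx]]) beta_i["beta4"] <- params$beta4[[tx]]
    ind_i <- matrix(data$indicators[i, -n_t, ], ncol = 3L,
                    dimnames = list(NULL, c("P2", "P3", "P4")))
    drift <- growth_mean(beta_i, ind_i) +
      climate_term(params$gamma[i], data$anomaly[i, -n_t])
    proc <- proc + sum(stats::dnorm(states$logx[i, -1L],
                                    states$logx[i, -n_t] + drift,
                                    params$sigma_x[i], log = TRUE))
  }
  lambda <- exp(states$loglambda)
  eff_obs <- sum(stats::dpois(z, lambda, log = TRUE))
  if (any(data$effort_missing)) {   # zero-truncation of latent counts
    eff_obs <- eff_obs -
      sum(log(1 - exp(-lambda[data$effort_missing])))
  }
  eff_proc <- sum(stats::dnorm(states$loglambda[-1L],
                               states$loglambda[-n_t],
                               params$sigma_lambda, log = TRUE))
  anchors <- init_anchors(data)
  prior <- sum(vapply(seq_len(n_i), function(i) {
    mvnorm_logpdf(c(params$beta[i, ], params$gamma[i]), params$mu,
                  params$Sigma)
  }, numeric(1L))) +
    sum(stats::dnorm(params$beta4, 0, priors$beta4_sd, log = TRUE)) +
    sum(stats::dnorm(states$logx[, 1L], anchors$logx1, priors$init_sd,
                     log = TRUE)) +
    stats::dnorm(states$loglambda[1L], anchors$loglambda1, priors$init_sd,
                 log = TRUE)
  hyper <- sum(stats::dnorm(params$mu, 0, priors$mu_sd, log = TRUE)) +
    invwishart_logpdf(params$Sigma, priors$Sigma_df, priors$Sigma_scale) -
    length(sds) * log(priors$sd_max)
  comp <- c(observation = obs, process = proc, effort_obs = eff_obs,
            effort_process = eff_proc, prior = prior, hyperprior = hyper)
  if (parts) comp else sum(comp)
}
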