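#' Simulation configuration
#'
#' Collects every knob of the generative model: taxon-level true growth
#' coefficients, temperature-anomaly effects, observation/process noise,
#' the effort random walk, the trending temperature series, effort
#' missingness and the zero-catch floor. Defaults (see [preset_community()])
#' describe an 8-taxon, 1966-2022 community patterned on a lake cyprinid
#' fishery: five taxa whose decline starts in period 2 and three whose
#' decline starts in period 3, plus positive restoration effects for the
#' two period-4 taxa.
#'
#' @param taxa character vector of taxon names.
#' @param schemes named list of [period_scheme()] per taxon.
#' @param beta matrix `[taxon, c("beta1","beta2","beta3")]` of log-growth
#'   coefficients (units: log grams-per-fisher per year).
#' @param beta4 named numeric, restoration effect for taxa with a period 4.
#' @param gamma numeric per taxon, anomaly effect (per degree C).
#' @param sigma_x,sigma_y numeric per taxon, process / observation SDs on
#'   the log scale.
#' @param logx1_mean,logx1_sd mean and SD of the initial log CPUE draw per
#'   taxon (`logx1_sd = 0` makes initial states deterministic).
#' @param lambda1 initial expected effort (fishers).
#' @param sigma_lambda log-scale SD of the effort random walk.
#' @param temp_base,temp_trend,temp_sd temperature intercept (degrees C at
#'   the first year), linear trend (degrees C per year) and iid noise SD.
#' @param missing_years integer vector of years whose effort is masked.
#' @param zero_floor catch value substituted for zeros downstream (grams).
#' @param inject_zero_years optional list `taxon -> years` whose generated
#'   catch is overwritten with 0 to exercise the flooring path.
#' @param seed integer seed; all generated quantities are reproducible from
#'   `(config, seed)`.
#' @return List of class `sim_config`.
#' @seealso [simulate_community()], [preset_community()]
#' @export
sim_config <- function(taxa, schemes, beta, beta4 = numeric(), gamma,
                       sigma_x, sigma_y,
                       logx1_mean = 8.5, logx1_sd = 0.5,
                       lambda1 = 200, sigma_lambda = 0.05,
                       temp_base = 14.2, temp_trend = 0.03, temp_sd = 0.4,
                       missing_years = integer(),
                       zero_floor = 50,
                       inject_zero_years = list(),
                       seed = 1L) {
  n <- length(taxa)
  beta <- as.matrix(beta)
  if (nrow(beta) != n || ncol(beta) != 3L) {
    stop("beta must be a [taxon x 3] matrix")
  }
  rownames(beta) <- taxa
  colnames(beta) <- c("beta1", "beta2", "beta3")
  rec <- function(x, what) {
    x <- rep_len(as.numeric(x), n)
    if (any(!is.finite(x))) stop("non-finite ", what)
    stats::setNames(x, taxa)
  }
  gamma <- rec(gamma, "gamma"); sigma_x <- rec(sigma_x, "sigma_x")
  sigma_y <- rec(sigma_y, "sigma_y")
  logx1_mean <- rec(logx1_mean, "logx1_mean")
  if (any(sigma_x < 0) || any(sigma_y < 0) || sigma_lambda < 0 ||
      temp_sd < 0 || logx1_sd < 0) stop("SDs must be >= 0")
  if (!all(is.finite(beta)) || !all(is.finite(unlist(beta4)))) {
    stop("non-finite growth coefficient")
  }
  if (lambda1 <= 0) stop("lambda1 must be > 0")
  restoration <- names(Filter(function(s) s$has_period4, schemes))
  if (!setequal(names(beta4), restoration)) {
    stop("beta4 must be named exactly by the restoration taxa: ",
         paste(restoration, collapse = ", "))
  }
  years <- schemes[[1L]]$first_year:schemes[[1L]]$last_year
  if (length(missing_years) && !all(missing_years %in% years)) {
    stop("missing_years outside the modelled year range")
  }
  structure(list(
    taxa = taxa, schemes = schemes, years = years,
    beta = beta, beta4 = unlist(beta4), gamma = gamma,
    sigma_x = sigma_x, sigma_y = sigma_y,
    logx1_mean = logx1_mean, logx1_sd = logx1_sd,
    lambda1 = lambda1, sigma_lambda = sigma_lambda,
    temp_base = temp_base, temp_trend = temp_trend, temp_sd = temp_sd,
    missing_years = as.integer(missing_years), zero_floor = zero_floor,
    inject_zero_years = inject_zero_years, seed = as.integer(seed)),
    class = "sim_config")
}

#' Community preset with a two-group decline structure
#'
#' Five taxa ("group 1": the periodic strategists) have negative period-2
#' and period-3 growth; three taxa ("group 2": the opportunists) decline
#' only from period 3. The two restoration taxa get positive period-4
#' effects. Magnitudes are of order |beta| <= 0.3 so that period growth
#' rates stay in the plausible -0.3..0.1 range; noise SDs are typical of
#' log-scale annual fishery records.
#'
#' @param seed integer seed stored in the config.
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_community <- function(seed = 1L, ...) {
  taxa <- biwa_taxa()
  schemes <- default_schemes(taxa)
  # group 1 (decline from period 2): Opsariichthys, Ischikauia,
  # Sarcocheilichthys, Cyprinus, Carassius; group 2 (decline from period 3):
  # Zacco, Gnathopogon, Squalidus.
  g1 <- c("Opsariichthys uncirostris", "Ischikauia steenackeri",
          "Sarcocheilichthys spp.", "Cyprinus carpio", "Carassius spp.")
  beta <- matrix(0, length(taxa), 3,
                 dimnames = list(taxa, c("beta1", "beta2", "beta3")))
  beta[, "beta1"] <- 0.05
  beta[, "beta2"] <- ifelse(taxa %in% g1, -0.25, -0.02)
  beta[, "beta3"] <- ifelse(taxa %in% g1, -0.20, -0.30)
  beta4 <- c("Ischikauia steenackeri" = 0.15,
             "Gnathopogon caerulescens" = 0.25)
  gamma <- stats::setNames(rep(-0.05, length(taxa)), taxa)
  gamma["Cyprinus carpio"] <- 0.02
  defaults <- list(
    taxa = taxa, schemes = schemes, beta = beta, beta4 = beta4,
    gamma = gamma, sigma_x = 0.15, sigma_y = 0.30,
    logx1_mean = 8.5, logx1_sd = 0.5,
    lambda1 = 200, sigma_lambda = 0.05,
    temp_base = 14.2, temp_trend = 0.03, temp_sd = 0.4,
    missing_years = c(1973L, 1974L, 1988L, 2005L),
    seed = seed)
  overrides <- list(...)
  args <- defaults
  args[names(overrides)] <- overrides   # replace wholesale, never merge
  do.call(sim_config, args)
}

#' Simulate the annual temperature series
#'
#' Linear warming trend plus iid Gaussian noise, emulating a long-term
#' air-temperature record.
#'
#' @param config a `sim_config`.
#' @param seed optional override of `config$seed`.
#' @return data.frame with columns `year`, `temp_c`.
#' @export
simulate_temperature <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  yrs <- config$years
  temp <- config$temp_base + config$temp_trend * (yrs - yrs[1L]) +
    stats::rnorm(length(yrs), 0, config$temp_sd)
  data.frame(year = yrs, temp_c = temp)
}

#' Simulate the shared effort series
#'
#' Latent expected effort follows a log random walk; observed effort is a
#' Poisson draw around it. Years in `config$missing_years` are flagged
#' missing in the observed series but retained in the truth record.
#'
#' @param config a `sim_config`.
#' @param seed optional override of `config$seed`.
#' @return List with `effort` (data.frame `year`, `n_fishers`, `missing`)
#'   and `lambda` (latent expected effort per year).
#' @export
simulate_effort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  yrs <- config$years
  n <- length(yrs)
  loglam <- numeric(n)
  loglam[1L] <- log(config$lambda1)
  if (n > 1L) {
    steps <- stats::rnorm(n - 1L, 0, config$sigma_lambda)
    loglam[-1L] <- loglam[1L] + cumsum(steps)
  }
  lambda <- exp(loglam)
  z <- stats::rpois(n, lambda)
  missing <- yrs %in% config$missing_years
  eff <- data.frame(year = yrs,
                    n_fishers = ifelse(missing, NA_integer_, z),
                    missing = missing)
  list(effort = eff, lambda = stats::setNames(lambda, yrs),
       z_true = stats::setNames(z, yrs))
}

#' Simulate a full community panel from the generative model
#'
#' Runs the exact state-space model forward: latent log-CPUE random walks
#' with period-specific drift plus an anomaly term, lognormal catch
#' observation around log CPUE + log effort, and the Poisson effort layer.
#' The temperature, effort and catch streams use independent substreams
#' derived from the seed so that each marginal series is reproducible.
#'
#' @param config a `sim_config`.
#' @param seed optional override of `config$seed`.
#' @return List of class `synthetic_panel` with elements `panel` (a
#'   [fishery_panel()]) and `truth` (all latent states and parameters).
#' @export
simulate_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  yrs <- config$years
  n_t <- length(yrs)
  taxa <- config$taxa
  temp <- simulate_temperature(config, seed = seed + 1L)
  eff <- simulate_effort(config, seed = seed + 2L)
  ind <- build_indicators(config$schemes, yrs)
  anom <- compute_anomaly(temp, config$schemes, yrs)

  set.seed(seed + 3L)
  logx <- matrix(NA_real_, length(taxa), n_t, dimnames = list(taxa, yrs))
  drift <- matrix(NA_real_, length(taxa), n_t - 1L,
                  dimnames = list(taxa, yrs[-1L]))
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    b4 <- if (tx %in% names(config$beta4)) config$beta4[[tx]] else 0
    # drift into year t uses indicators and anomaly at t-1
    R <- config$beta[tx, "beta1"] +
      config$beta[tx, "beta2"] * ind[tx, -n_t, "P2"] +
      config$beta[tx, "beta3"] * ind[tx, -n_t, "P3"] +
      b4 * ind[tx, -n_t, "P4"]
    S <- config$gamma[[tx]] * anom[tx, -n_t]
    drift[i, ] <- R + S
    logx[i, 1L] <- stats::rnorm(1, config$logx1_mean[[tx]], config$logx1_sd)
    for (t in 2:n_t) {
      logx[i, t] <- stats::rnorm(1, logx[i, t - 1L] + drift[i, t - 1L],
                                 config$sigma_x[[tx]])
    }
  }
  logz <- log(pmax(eff$z_true, 1L))
  logy <- logx + matrix(logz, length(taxa), n_t, byrow = TRUE) +
    matrix(stats::rnorm(length(taxa) * n_t, 0, rep(config$sigma_y, n_t)),
           length(taxa), n_t)
  catch <- exp(logy)
  for (tx in names(config$inject_zero_years)) {
    zy <- as.character(config$inject_zero_years[[tx]])
    catch[tx, zy] <- 0
  }

  panel <- fishery_panel(catch = catch, effort = eff$effort,
                         temperature = temp, schemes = config$schemes)
  truth <- list(beta = config$beta, beta4 = config$beta4,
                gamma = config$gamma, sigma_x = config$sigma_x,
                sigma_y = config$sigma_y, sigma_lambda = config$sigma_lambda,
                logx = logx, drift = drift,
                lambda = eff$lambda, z = eff$z_true,
                seed = seed)
  structure(list(panel = panel, truth = truth, config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic fishery panel:", length(x$config$taxa), "taxa x",
      length(x$config$years), "years (seed", x$truth$seed, ")\n")
  print(x$panel)
  invisible(x)
}
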