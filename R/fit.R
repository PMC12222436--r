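#' Fit the hierarchical state-space model by MCMC
#'
#' Metropolis-within-Gibbs sampler exploiting the model's conditional
#' structure: latent log-CPUE chains are drawn jointly per taxon by
#' forward-filter backward-sampling (exact, via the linear-Gaussian
#' reduction given effort), growth/anomaly coefficients and all variances
#' have conjugate updates, the community hyper-mean and covariance use
#' Normal / inverse-Wishart conjugacy, latent log expected effort is slice
#' sampled, and latent effort counts at missing years are drawn exactly by
#' discrete enumeration of their zero-truncated full conditional.
#'
#' The defaults are a reduced schedule that a desk machine finishes in
#' seconds; for a heavyweight reference run (6 chains, 1000 warmup,
#' 100000 iterations thinned by 100) pass `n_chains = 6, n_iter = 101000,
#' warmup = 1000, thin = 100`.
#'
#' @param data a [prepare_data()] object.
#' @param priors an [default_priors()] object.
#' @param n_chains number of independent chains (>= 2 for R-hat).
#' @param n_iter total iterations per chain, including warmup.
#' @param warmup iterations discarded per chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; the whole fit is reproducible from it.
#' @param monitor character subset of
#'   `c("beta", "gamma", "sigma", "hyper", "states", "effort")`.
#' @param fix named list of quantities to hold at fixed values instead of
#'   sampling: `beta` + `gamma` (jointly), `beta4`, `sigma_y`, `sigma_x`,
#'   `sigma_lambda`, `mu`, `Sigma`.
#' @param effort_mode `"exact"` (latent counts sampled by enumeration) or
#'   `"relaxed"` (missing counts pinned to round(lambda); documented
#'   approximation, flagged in the returned metadata).
#' @return Object of class `ssm_draws`: `draws` array
#'   `[iteration, chain, quantity]`, per-quantity `rhat`, `converged`
#'   flag (all R-hat < 1.1), and the sampler config.
#' @export
fit_ssm <- function(data, priors = default_priors(),
                    n_chains = 4L, n_iter = 5000L, warmup = 1000L,
                    thin = 1L, seed = 1L,
                    monitor = c("beta", "gamma", "sigma", "hyper",
                                "states", "effort"),
                    fix = list(),
                    effort_mode = c("exact", "relaxed")) {
  stopifnot(inherits(data, "prepared_data"), n_iter > warmup, thin >= 1L)
  effort_mode <- match.arg(effort_mode)
  monitor <- match.arg(monitor, several.ok = TRUE,
                       choices = c("beta", "gamma", "sigma", "hyper",
                                   "states", "effort"))
  if (xor(is.null(fix$beta), is.null(fix$gamma))) {
    stop("fix beta and gamma together (one coefficient block)")
  }
  n_i <- length(data$taxa); n_t <- length(data$years)
  taxa <- data$taxa; years <- data$years
  rest <- data$restoration
  miss <- which(data$effort_missing)
  L <- data$log_catch
  anchors <- init_anchors(data)
  init_var <- priors$init_sd^2

  # fixed per-taxon design matrices for the increment regression:
  # columns (1, P2, P3, T [, P4]) at years 1..T-1
  X <- lapply(seq_len(n_i), function(i) {
    Xi <- cbind(1, data$indicators[i, -n_t, "P2"],
                data$indicators[i, -n_t, "P3"],
                data$anomaly[i, -n_t])
    if (rest[[i]]) Xi <- cbind(Xi, data$indicators[i, -n_t, "P4"])
    Xi
  })
  XtX <- lapply(X, crossprod)
  k_i <- vapply(X, ncol, integer(1L))

  qn <- monitored_names(monitor, taxa, years, rest, miss)
  n_keep <- (n_iter - warmup) %/% thin
  draws <- array(NA_real_, dim = c(n_keep, n_chains, length(qn)),
                 dimnames = list(NULL, paste0("chain", seq_len(n_chains)), qn))

  set.seed(seed)
  for (ch in seq_len(n_chains)) {
    st <- init_state(data, priors, X, fix, anchors)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      st <- gibbs_sweep(st, data, priors, X, XtX, k_i, fix, anchors,
                        init_var, miss, effort_mode)
      if (it > warmup && (it - warmup) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ch, ] <- flatten_state(st, monitor, taxa, rest, miss)
      }
    }
  }

  rh <- apply(draws, 3L, function(m) rhat(m))
  structure(list(
    draws = draws, rhat = rh,
    converged = all(rh < 1.1, na.rm = TRUE),
    config = list(n_chains = n_chains, n_iter = n_iter, warmup = warmup,
                  thin = thin, seed = seed, monitor = monitor,
                  effort_mode = effort_mode,
                  fixed = names(fix)),
    taxa = taxa, years = years, restoration = rest,
    missing_years = years[miss]),
    class = "ssm_draws")
}

monitored_names <- function(monitor, taxa, years, rest, miss) {
  qn <- character()
  if ("beta" %in% monitor) {
    qn <- c(qn, paste0("beta1[", taxa, "]"), paste0("beta2[", taxa, "]"),
            paste0("beta3[", taxa, "]"),
            if (any(rest)) paste0("beta4[", taxa[rest], "]"))
  }
  if ("gamma" %in% monitor) qn <- c(qn, paste0("gamma[", taxa, "]"))
  if ("sigma" %in% monitor) {
    qn <- c(qn, paste0("sigma_y[", taxa, "]"), paste0("sigma_x[", taxa, "]"),
            "sigma_lambda")
  }
  if ("hyper" %in% monitor) {
    ut <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
    qn <- c(qn, paste0("mu[", 1:4, "]"),
            paste0("Sigma[", ut[, 1L], ",", ut[, 2L], "]"))
  }
  if ("states" %in% monitor) {
    qn <- c(qn, paste0("logx[", rep(taxa, times = length(years)), ",",
                       rep(years, each = length(taxa)), "]"))
  }
  if ("effort" %in% monitor) {
    qn <- c(qn, paste0("loglambda[", years, "]"),
            if (length(miss)) paste0("z[", years[miss], "]"))
  }
  qn
}

flatten_state <- function(st, monitor, taxa, rest, miss) {
  out <- numeric()
  if ("beta" %in% monitor) {
    out <- c(out, st$coef[, 1L], st$coef[, 2L], st$coef[, 3L],
             st$beta4[rest])
  }
  if ("gamma" %in% monitor) out <- c(out, st$coef[, 4L])
  if ("sigma" %in% monitor) {
    out <- c(out, sqrt(st$sig2y), sqrt(st$sig2x), sqrt(st$sig2lam))
  }
  if ("hyper" %in% monitor) {
    out <- c(out, st$mu, st$Sigma[upper.tri(st$Sigma, diag = TRUE)])
  }
  if ("states" %in% monitor) out <- c(out, as.vector(st$u))
  if ("effort" %in% monitor) out <- c(out, st$v, st$z[miss])
  out
}

init_state <- function(data, priors, X, fix, anchors) {
  n_i <- length(data$taxa); n_t <- length(data$years)
  z <- data$effort
  if (any(data$effort_missing)) {
    obs_idx <- which(!data$effort_missing)
    z[data$effort_missing] <- pmax(1, round(exp(
      stats::approx(obs_idx, log(z[obs_idx]), xout = which(data$effort_missing),
                    rule = 2)$y)))
  }
  v <- log(z) + stats::rnorm(n_t, 0, 0.05)
  u <- data$log_catch - matrix(log(z), n_i, n_t, byrow = TRUE) +
    matrix(stats::rnorm(n_i * n_t, 0, 0.1), n_i, n_t)
  coef <- matrix(0, n_i, 4L)   # beta1, beta2, beta3, gamma
  beta4 <- stats::setNames(rep(0, n_i), data$taxa)
  sig2x <- numeric(n_i)
  for (i in seq_len(n_i)) {
    du <- diff(u[i, ])
    th <- tryCatch(stats::coef(stats::lm.fit(X[[i]], du)),
                   error = function(e) rep(0, ncol(X[[i]])))
    th[!is.finite(th)] <- 0
    th <- th + stats::rnorm(length(th), 0, 0.05)
    coef[i, ] <- th[1:4]
    if (ncol(X[[i]]) == 5L) beta4[i] <- th[5L]
    sig2x[i] <- max(1e-4, stats::var(du - X[[i]] %*% th)) *
      stats::runif(1, 0.5, 2)
  }
  sig2y <- pmax(1e-4, rep(stats::var(as.vector(
    data$log_catch - u - matrix(log(z), n_i, n_t, byrow = TRUE))), n_i)) *
    stats::runif(n_i, 0.5, 2)
  st <- list(u = u, v = v, z = z, coef = coef, beta4 = beta4,
             sig2y = sig2y, sig2x = sig2x,
             sig2lam = max(1e-4, stats::var(diff(v))) * stats::runif(1, 0.5, 2),
             mu = colMeans(coef) + stats::rnorm(4, 0, 0.02),
             Sigma = (if (n_i > 1L) stats::cov(coef) else matrix(0, 4, 4)) +
               diag(0.02, 4))
  apply_fix(st, fix, data)
}

apply_fix <- function(st, fix, data) {
  if (!is.null(fix$beta)) st$coef[, 1:3] <- as.matrix(fix$beta)
  if (!is.null(fix$gamma)) st$coef[, 4L] <- fix$gamma
  if (!is.null(fix$beta4)) st$beta4[names(fix$beta4)] <- fix$beta4
  if (!is.null(fix$sigma_y)) st$sig2y <- rep_len(fix$sigma_y^2, nrow(st$coef))
  if (!is.null(fix$sigma_x)) st$sig2x <- rep_len(fix$sigma_x^2, nrow(st$coef))
  if (!is.null(fix$sigma_lambda)) st$sig2lam <- fix$sigma_lambda^2
  if (!is.null(fix$mu)) st$mu <- fix$mu
  if (!is.null(fix$Sigma)) st$Sigma <- fix$Sigma
  st
}

# inverse-gamma draw for a variance with uniform-on-SD prior, truncated at
# sd_max^2 (retry a handful of times; the bound is essentially never hit)
draw_var <- function(n_obs, ss, sd_max) {
  shape <- (n_obs - 1) / 2
  for (r in 1:20) {
    v <- 1 / stats::rgamma(1L, shape, rate = ss / 2)
    if (v <= sd_max^2) return(v)
  }
  sd_max^2
}

gibbs_sweep <- function(st, data, priors, X, XtX, k_i, fix, anchors,
                        init_var, miss, effort_mode) {
  n_i <- length(data$taxa); n_t <- length(data$years)
  SigInv <- chol2inv(chol(st$Sigma))
  up <- sweep_taxa_cpp(
    data$log_catch, log(st$z), X, st$u, st$coef, st$beta4,
    unname(data$restoration), st$sig2y, st$sig2x, SigInv, st$mu,
    priors$beta4_sd, priors$sd_max, anchors$logx1, init_var,
    fix_coef = !is.null(fix$beta), fix_beta4 = !is.null(fix$beta4),
    fix_sigy = !is.null(fix$sigma_y), fix_sigx = !is.null(fix$sigma_x))
  st$u <- up$u
  st$coef <- up$coef
  st$beta4[] <- up$beta4
  st$sig2y <- as.vector(up$sig2y)
  st$sig2x <- as.vector(up$sig2x)

  # latent effort counts at missing years
  for (tt in miss) {
    if (effort_mode == "relaxed") {
      st$z[tt] <- max(1L, round(exp(st$v[tt])))
    } else {
      st$z[tt] <- draw_missing_z_cpp(st$v[tt], data$log_catch[, tt],
                                     st$u[, tt], st$sig2y)
    }
  }
  trunc <- data$effort_missing & effort_mode == "exact"
  st$v <- slice_loglambda_cpp(st$v, st$z, trunc, st$sig2lam,
                              anchors$loglambda1, init_var)
  if (is.null(fix$sigma_lambda)) {
    st$sig2lam <- draw_var(n_t - 1L, sum(diff(st$v)^2), priors$sd_max)
  }

  # community hyper-parameters over (beta1, beta2, beta3, gamma)
  if (is.null(fix$mu)) {
    prec <- n_i * SigInv + diag(1 / priors$mu_sd^2, 4L)
    ch <- chol(prec)
    m <- backsolve(ch, backsolve(ch, SigInv %*% colSums(st$coef),
                                 transpose = TRUE))
    st$mu <- as.vector(m + backsolve(ch, stats::rnorm(4L)))
  }
  if (is.null(fix$Sigma)) {
    dev <- sweep(st$coef, 2L, st$mu)
    S <- priors$Sigma_scale + crossprod(dev)
    W <- stats::rWishart(1L, priors$Sigma_df + n_i, chol2inv(chol(S)))[, , 1L]
    st$Sigma <- chol2inv(chol(W))
  }
  st
}

#' @export
print.ssm_draws <- function(x, ...) {
  cfg <- x$config
  cat("ssm_draws:", dim(x$draws)[1L], "draws x", cfg$n_chains, "chains x",
      dim(x$draws)[3L], "quantities\n")
  cat("  max R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
      if (x$converged) "(converged, all < 1.1)" else "(NOT all < 1.1)", "\n")
  if (length(cfg$fixed)) cat("  fixed:", paste(cfg$fixed, collapse = ", "), "\n")
  if (cfg$effort_mode != "exact") cat("  effort mode:", cfg$effort_mode, "\n")
  invisible(x)
}

#' Extract monitored draws as a matrix
#'
#' @param fit an `ssm_draws` object.
#' @param pattern optional regular expression selecting quantity names.
#' @return Matrix `[chain x iteration, quantity]` (chains stacked).
#' @export
extract_draws <- function(fit, pattern = NULL) {
  stopifnot(inherits(fit, "ssm_draws"))
  qn <- dimnames(fit$draws)[[3L]]
  sel <- if (is.null(pattern)) seq_along(qn) else grep(pattern, qn)
  if (!length(sel)) stop("no monitored quantity matches '", pattern, "'")
  out <- apply(fit$draws[, , sel, drop = FALSE], 3L, identity)
  matrix(out, ncol = length(sel), dimnames = list(NULL, qn[sel]))
}
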