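summarise_draws_vec <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(median = q[3L], ci50_lo = q[2L], ci50_hi = q[4L],
             ci95_lo = q[1L], ci95_hi = q[5L],
             p_decline = mean(x < 0), p_growth = mean(x > 0))
}

#' Per-taxon average log growth rates by period
#'
#' Derived quantities computed draw by draw: period 1 growth is `beta1`,
#' period 2 is `beta1 + beta2`, period 3 is `beta1 + beta3`, and period 4
#' (restoration taxa only) is `beta1 + beta4`. Reports the posterior
#' median, equal-tailed 50% and 95% credible intervals, and the posterior
#' probabilities of decline (rate < 0) and growth (rate > 0).
#'
#' @param fit an `ssm_draws` with the `beta` group monitored.
#' @return data.frame with one row per taxon x period.
#' @export
derive_period_growth <- function(fit) {
  stopifnot(inherits(fit, "ssm_draws"))
  out <- list()
  for (tx in fit$taxa) {
    b1 <- extract_draws(fit, paste0("^beta1\\[", tx, "\\]$"))[, 1L]
    b2 <- extract_draws(fit, paste0("^beta2\\[", tx, "\\]$"))[, 1L]
    b3 <- extract_draws(fit, paste0("^beta3\\[", tx, "\\]$"))[, 1L]
    g <- list("1" = b1, "2" = b1 + b2, "3" = b1 + b3)
    if (fit$restoration[[tx]]) {
      g[["4"]] <- b1 + extract_draws(fit,
                                     paste0("^beta4\\[", tx, "\\]$"))[, 1L]
    }
    for (p in names(g)) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(taxon = tx, period = as.integer(p)),
        summarise_draws_vec(g[[p]]))
    }
  }
  do.call(rbind, out)
}

#' Community-level growth summaries from the hyper-mean
#'
#' The community average growth rate per period is a function of the
#' hyper-mean vector draws (not the average of taxon-level coefficients):
#' period 1 = `mu1`, period 2 = `mu1 + mu2`, period 3 = `mu1 + mu3`; the
#' community temperature effect is `mu4` itself.
#'
#' @param fit an `ssm_draws` with the `hyper` group monitored.
#' @return data.frame with rows period 1..3 and `temperature`.
#' @export
derive_community_growth <- function(fit) {
  stopifnot(inherits(fit, "ssm_draws"))
  mu <- extract_draws(fit, "^mu\\[")
  g <- list("period1" = mu[, "mu[1]"],
            "period2" = mu[, "mu[1]"] + mu[, "mu[2]"],
            "period3" = mu[, "mu[1]"] + mu[, "mu[3]"],
            "temperature" = mu[, "mu[4]"])
  do.call(rbind, lapply(names(g), function(nm) {
    cbind(data.frame(quantity = nm), summarise_draws_vec(g[[nm]]))
  }))
}

#' Posterior CPUE trajectories
#'
#' Pointwise posterior median and equal-tailed 95% interval of the CPUE
#' `x = exp(log x)` for every taxon and year.
#'
#' @param fit an `ssm_draws` with the `states` group monitored.
#' @return data.frame with columns taxon, year, q2.5, median, q97.5
#'   (grams per fisher).
#' @export
cpue_trajectory <- function(fit) {
  stopifnot(inherits(fit, "ssm_draws"))
  out <- vector("list", length(fit$taxa))
  for (i in seq_along(fit$taxa)) {
    tx <- fit$taxa[i]
    d <- exp(extract_draws(fit, paste0("^logx\\[", tx, ",")))
    yr <- as.integer(sub(".*,(\\d+)\\]$", "\\1", colnames(d)))
    q <- apply(d, 2L, stats::quantile, c(0.025, 0.5, 0.975), names = FALSE)
    out[[i]] <- data.frame(taxon = tx, year = yr, q2.5 = q[1L, ],
                           median = q[2L, ], q97.5 = q[3L, ])[order(yr), ]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
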