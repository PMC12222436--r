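#' Kalman filter/smoother for the single-taxon linear-Gaussian reduction
#'
#' With effort known and fixed, the per-taxon model is a scalar
#' linear-Gaussian state-space model on the log scale:
#' `w_t = u_t + eps_t` (observation, variance `sigy2`) and
#' `u_t = u_{t-1} + d_{t-1} + eta_t` (process, variance `sigx2`), with
#' `u_1 ~ N(m0, s02)`. Returns Rauch-Tung-Striebel smoothed means and
#' variances plus the exact marginal log-likelihood of `w`.
#'
#' This deterministic recursion is an independent code path from the
#' sampling-based forward-filter backward-sampler used by [fit_ssm()], and
#' serves as its oracle.
#'
#' @param w observations (log catch minus log effort), length T.
#' @param drift process drifts `d_1..d_{T-1}` (into years 2..T).
#' @param sigy2,sigx2 observation / process variances.
#' @param m0,s02 initial-state prior mean and variance.
#' @return List with `mean`, `var` (smoothed, length T), `filter_mean`,
#'   `filter_var`, and `loglik`.
#' @export
kalman_smoother <- function(w, drift, sigy2, sigx2, m0, s02) {
  T <- length(w)
  stopifnot(length(drift) == T - 1L, sigy2 > 0, sigx2 >= 0, s02 > 0)
  m <- P <- mp <- Pp <- numeric(T)
  loglik <- 0
  for (t in seq_len(T)) {
    if (t == 1L) {
      mp[t] <- m0; Pp[t] <- s02
    } else {
      mp[t] <- m[t - 1L] + drift[t - 1L]
      Pp[t] <- P[t - 1L] + sigx2
    }
    S <- Pp[t] + sigy2
    loglik <- loglik + stats::dnorm(w[t], mp[t], sqrt(S), log = TRUE)
    K <- Pp[t] / S
    m[t] <- mp[t] + K * (w[t] - mp[t])
    P[t] <- (1 - K) * Pp[t]
  }
  h <- H <- numeric(T)
  h[T] <- m[T]; H[T] <- P[T]
  for (t in (T - 1L):1L) {
    C <- P[t] / Pp[t + 1L]
    h[t] <- m[t] + C * (h[t + 1L] - mp[t + 1L])
    H[t] <- P[t] + C^2 * (H[t + 1L] - Pp[t + 1L])
  }
  list(mean = h, var = H, filter_mean = m, filter_var = P, loglik = loglik)
}
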