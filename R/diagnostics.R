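#' Potential scale reduction factor (R-hat)
#'
#' `rhat()` is the rank-normalized split-R-hat of Vehtari et al. (2021):
#' chains are split in half, all draws are rank-normalized through the
#' normal quantile function, and the classic between/within ratio is taken
#' as the maximum of the bulk and tail (folded) versions.
#' `rhat_classic()` is the original Gelman-Rubin formula on the raw draws
#' (no splitting), kept as the textbook reference.
#'
#' Values near 1 indicate mixing; the conventional convergence threshold
#' used throughout this package is R-hat < 1.1.
#'
#' @param draws matrix `[iteration, chain]` of posterior draws for one
#'   quantity.
#' @return Scalar R-hat (NA for constant draws).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("R-hat needs at least 2 chains")
  if (nrow(draws) < 4L) stop("R-hat needs at least 4 draws per chain")
  if (stats::var(as.vector(draws)) == 0) return(NA_real_)
  bulk <- rhat_classic(split_chains(z_scale(draws)))
  folded <- abs(draws - stats::median(draws))
  tail <- rhat_classic(split_chains(z_scale(folded)))
  max(bulk, tail)
}

#' @rdname rhat
#' @export
rhat_classic <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2L) stop("R-hat needs at least 2 chains")
  chain_means <- colMeans(draws)
  B <- n * stats::var(chain_means)
  W <- mean(apply(draws, 2L, stats::var))
  if (W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_chains <- function(draws) {
  n <- nrow(draws)
  h <- n %/% 2L
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1L):n, , drop = FALSE])
}

z_scale <- function(draws) {
  r <- rank(draws, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}
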