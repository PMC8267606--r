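#' Graded-response category probabilities under the bifactor model
#'
#' The model is the logistic graded-response model with a bifactor latent
#' structure: the probability of responding in category `k` or above is
#' `plogis(a0 * theta0 + ag * thetag - c_k)`, with ordered thresholds
#' `c_1 < ... < c_{K-1}`, so the probability of category `k` (0-based) is the
#' difference of adjacent cumulative probabilities. No 1.7 scaling constant is
#' applied: slopes are on the logistic metric.
#'
#' @param a0 primary-dimension slope.
#' @param ag group-factor slope.
#' @param thresholds strictly increasing numeric vector of length `K - 1`.
#' @param theta0,thetag numeric vectors (recycled to a common length) of
#'   latent values at which to evaluate.
#' @return a `length(theta)` x `K` matrix of category probabilities; rows sum
#'   to 1.
#' @export
#' @examples
#' p <- grm_probs(1.2, 0.5, c(-1, 0, 1), theta0 = 0, thetag = 0)
#' rowSums(p)  # 1
grm_probs <- function(a0, ag, thresholds, theta0, thetag = 0) {
  eta <- a0 * theta0 + ag * thetag
  n <- length(eta)
  K <- length(thresholds) + 1L
  # cumulative P(Y >= k), k = 1..K-1, columns ordered
  cum <- stats::plogis(outer(eta, thresholds, `-`))
  p <- matrix(0, n, K)
  p[, 1L] <- 1 - cum[, 1L]
  if (K > 2L) {
    p[, 2:(K - 1L)] <- cum[, 1:(K - 2L), drop = FALSE] -
      cum[, 2:(K - 1L), drop = FALSE]
  }
  p[, K] <- cum[, K - 1L]
  p
}

#' Gauss-Hermite quadrature for a standard-normal prior
#'
#' Nodes and weights of `n`-point Gauss-Hermite quadrature rescaled so that
#' `sum(w * f(x))` approximates `E[f(Z)]` for `Z ~ N(0, 1)`. Computed by the
#' Golub-Welsch eigen decomposition of the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @export
gauss_hermite <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = sqrt(2) * e$values[ord],
       weights = e$vectors[1L, ord]^2)
}

#' Convert slopes to standardized loadings
#'
#' Under the normal-ogive-equivalent convention, the standardized loading on
#' each dimension is `a / sqrt(1 + a0^2 + ag^2)`. This is the scale on which
#' the 0.3 discrimination filter is defined.
#'
#' @param a0 primary slope(s).
#' @param ag group slope(s); defaults to 0.
#' @return data frame with columns `lambda0` and `lambdag`, both in \[-1, 1\].
#' @export
#' @examples
#' standardized_loadings(1, 0)  # lambda0 = 1 / sqrt(2)
standardized_loadings <- function(a0, ag = 0) {
  s <- sqrt(1 + a0^2 + ag^2)
  data.frame(lambda0 = a0 / s, lambdag = ag / s)
}

#' Convert standardized loadings to slopes
#'
#' Inverse of [standardized_loadings()]: given loadings with
#' `lambda0^2 + lambdag^2 < 1`, returns the logistic-metric slopes
#' `a = lambda / sqrt(1 - lambda0^2 - lambdag^2)`.
#'
#' @param lambda0 primary loading(s).
#' @param lambdag group loading(s); defaults to 0.
#' @return data frame with columns `a0` and `ag`.
#' @export
slopes_from_loadings <- function(lambda0, lambdag = 0) {
  comm <- lambda0^2 + lambdag^2
  if (any(comm >= 1)) stop("lambda0^2 + lambdag^2 must be < 1")
  s <- sqrt(1 - comm)
  data.frame(a0 = lambda0 / s, ag = lambdag / s)
}

# log category probabilities for one item over a (theta0, thetag) grid,
# guarded against log(0)
grm_log_probs <- function(a0, ag, thresholds, theta0, thetag = 0) {
  p <- grm_probs(a0, ag, thresholds, theta0, thetag)
  log(pmax(p, 1e-300))
}
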