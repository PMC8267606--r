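#' Expected a posteriori (EAP) score on the primary dimension
#'
#' Computes the posterior mean and posterior standard deviation of the primary
#' trait given a person's responses, under a standard-normal prior. The group
#' factors are marginalized: within each subdomain the joint likelihood of its
#' answered items is integrated over that subdomain's factor by Gauss-Hermite
#' quadrature, which is exact bookkeeping for the bifactor structure (factors
#' are mutually independent a priori).
#'
#' With no responses the prior itself is returned (`theta = 0`, `se = 1`).
#'
#' @param responses named integer vector (or list) of 0-based response codes,
#'   names are item ids; may be empty.
#' @param bank calibrated [item_bank()] containing the answered items.
#' @param quad_points nodes for the primary-dimension integral.
#' @param group_quad_points nodes for each group-factor integral.
#' @return list with `theta` (posterior mean, latent SD units), `se`
#'   (posterior SD) and `n_items`.
#' @export
eap_score <- function(responses, bank, quad_points = 49,
                      group_quad_points = 21) {
  responses <- unlist(responses)
  if (length(responses) == 0L) {
    return(list(theta = 0, se = 1, n_items = 0L))
  }
  if (is.null(names(responses))) stop("responses must be named by item id")
  idx <- match(names(responses), bank$item_id)
  if (anyNA(idx)) {
    stop("responses for items not in bank: ",
         paste(names(responses)[is.na(idx)], collapse = ", "))
  }
  gh0 <- gauss_hermite(quad_points)
  lpost <- log(gh0$weights) +
    eap_group_loglik(responses, bank, idx, gh0$nodes, group_quad_points)
  posterior_moments(gh0$nodes, lpost)
}

# sum over subdomains of log \int prod_j P_j dPhi(theta_g), on theta0 nodes
eap_group_loglik <- function(responses, bank, idx, nodes0, group_quad_points) {
  ghg <- gauss_hermite(group_quad_points)
  Q0 <- length(nodes0); Qg <- length(ghg$nodes)
  T0 <- rep(nodes0, times = Qg)
  Tg <- rep(ghg$nodes, each = Q0)
  total <- numeric(Q0)
  for (sd_g in unique(bank$subdomain[idx])) {
    pos <- which(bank$subdomain[idx] == sd_g)
    M <- numeric(Q0 * Qg)
    for (k in pos) {
      j <- idx[k]
      lp <- grm_log_probs(bank$a0[j], bank$ag[j], bank$thresholds[[j]], T0, Tg)
      M <- M + lp[, responses[[k]] + 1L]
    }
    M <- matrix(M, Q0, Qg)
    shift <- apply(M, 1L, max)
    total <- total + shift +
      log(pmax(as.vector(exp(M - shift) %*% ghg$weights), 1e-300))
  }
  total
}

posterior_moments <- function(nodes, lpost) {
  lpost <- lpost - max(lpost)
  w <- exp(lpost); w <- w / sum(w)
  m <- sum(w * nodes)
  v <- sum(w * (nodes - m)^2)
  list(theta = m, se = sqrt(max(v, 1e-12)), n_items = NA_integer_)
}

#' Fisher item information about the primary trait
#'
#' Information contributed by each item at given primary-trait values. Because
#' the adaptive test scores only the primary dimension, the default treats the
#' group factor as a nuisance integrated over its standard-normal prior
#' (marginal information: information of the prior-averaged category response
#' curves). `marginal = FALSE` instead conditions on the group factor at 0.
#' For a binary item with no group slope both reduce to the classical
#' `a0^2 * P * (1 - P)`.
#'
#' @param bank calibrated [item_bank()] (any subset of rows).
#' @param theta numeric vector of primary-trait values.
#' @param marginal integrate the group factor out (default) or pin it at 0.
#' @param group_quad_points quadrature nodes for the marginal version.
#' @return matrix of nonnegative information values, items x theta, with item
#'   ids as row names.
#' @export
item_information <- function(bank, theta, marginal = TRUE,
                             group_quad_points = 21) {
  validate_bank(bank, require_calibrated = TRUE)
  ghg <- if (marginal) gauss_hermite(group_quad_points) else
    list(nodes = 0, weights = 1)
  nt <- length(theta)
  out <- matrix(0, nrow(bank), nt, dimnames = list(bank$item_id, NULL))
  for (j in seq_len(nrow(bank))) {
    a0 <- bank$a0[j]; ag <- bank$ag[j]; cv <- bank$thresholds[[j]]
    K <- length(cv) + 1L
    pbar <- matrix(0, nt, K)    # prior-averaged category probabilities
    dbar <- matrix(0, nt, K)    # their derivatives in theta0
    for (q in seq_along(ghg$nodes)) {
      eta <- a0 * theta + ag * ghg$nodes[q]
      cum <- stats::plogis(outer(eta, cv, `-`))
      dcum <- a0 * cum * (1 - cum)
      pbar <- pbar + ghg$weights[q] * (cbind(1, cum) - cbind(cum, 0))
      dbar <- dbar + ghg$weights[q] * (cbind(0, dcum) - cbind(dcum, 0))
    }
    out[j, ] <- rowSums(dbar^2 / pmax(pbar, 1e-300))
  }
  out
}
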