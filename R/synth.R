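#' Default subdomain composition of the synthetic bank
#'
#' Five symptom subdomains sized 5 (exposure), 58 (mood/cognition),
#' 79 (arousal/reactivity), 18 (avoidance) and 51 (intrusion) items,
#' totalling 211.
#'
#' @return named integer vector.
#' @export
default_subdomain_sizes <- function() {
  c(exposure = 5L, mood_cognition = 58L, arousal_reactivity = 79L,
    avoidance = 18L, intrusion = 51L)
}

#' Generate a synthetic calibrated item bank
#'
#' Draws true bifactor graded-response parameters for an ordinal bank.
#' Standardized primary loadings of informative items are uniform on
#' `loading_range`; `n_poor_items` randomly placed items instead get primary
#' loadings at or below `poor_loading_max`, emulating poorly discriminating
#' items destined for the loading filter. Group loadings are uniform on
#' `group_loading_range`. Category thresholds are ordered draws around an
#' item-specific severity location spread over the trait continuum.
#'
#' @param n_items bank size.
#' @param subdomain_sizes named integer vector summing to `n_items`.
#' @param category_mix proportion of 5-category items (the rest have 4).
#' @param loading_range range of true primary loadings for informative items.
#' @param group_loading_range range of true group loadings.
#' @param n_poor_items number of planted near-zero-loading items.
#' @param poor_loading_max upper bound of a planted poor loading.
#' @param seed integer seed.
#' @return list with `bank` (calibrated [item_bank()]) and `truth` (data frame
#'   of true loadings with `is_poor` flags, plus the generation settings).
#' @export
gen_bank <- function(n_items = 211, subdomain_sizes = default_subdomain_sizes(),
                     category_mix = 0.5, loading_range = c(0.45, 0.90),
                     group_loading_range = c(0.2, 0.5),
                     n_poor_items = 0, poor_loading_max = 0.15, seed = 1L) {
  if (sum(subdomain_sizes) != n_items) {
    stop("subdomain_sizes must sum to n_items (",
         sum(subdomain_sizes), " != ", n_items, ")")
  }
  if (n_poor_items > n_items) stop("n_poor_items exceeds n_items")
  set.seed(seed)
  subdomain <- rep(names(subdomain_sizes), subdomain_sizes)
  item_id <- sprintf("it%03d", seq_len(n_items))
  n_cat <- ifelse(stats::runif(n_items) < category_mix, 5L, 4L)
  lambda0 <- stats::runif(n_items, loading_range[1], loading_range[2])
  is_poor <- rep(FALSE, n_items)
  if (n_poor_items > 0) {
    poor <- sample.int(n_items, n_poor_items)
    lambda0[poor] <- stats::runif(n_poor_items, 0, poor_loading_max)
    is_poor[poor] <- TRUE
  }
  # cap group loadings so each item's communality stays below 0.95
  hi_g <- pmin(group_loading_range[2], sqrt(pmax(0.95 - lambda0^2, 0)))
  lo_g <- pmin(group_loading_range[1], hi_g)
  lambdag <- stats::runif(n_items, lo_g, hi_g)
  sl <- slopes_from_loadings(lambda0, lambdag)
  thresholds <- vector("list", n_items)
  for (j in seq_len(n_items)) {
    mu <- stats::runif(1, -1.2, 1.8)       # item severity location
    b <- sort(stats::rnorm(n_cat[j] - 1L, mu, 0.7))
    b <- b + (seq_along(b) - 1L) * 1e-3    # guard strict ordering
    gaps <- pmax(diff(b), 0.25)            # keep categories distinguishable
    b <- b[1L] + c(0, cumsum(gaps))
    a_tot <- sqrt(sl$a0[j]^2 + sl$ag[j]^2)
    thresholds[[j]] <- b * max(a_tot, 0.3)
  }
  bank <- item_bank(item_id, subdomain, n_cat,
                    a0 = sl$a0, ag = sl$ag, thresholds = thresholds)
  truth <- data.frame(item_id = item_id, subdomain = subdomain,
                      lambda0 = lambda0, lambdag = lambdag, is_poor = is_poor,
                      stringsAsFactors = FALSE)
  list(bank = bank, truth = truth,
       settings = list(category_mix = category_mix,
                       loading_range = loading_range,
                       group_loading_range = group_loading_range,
                       poor_loading_max = poor_loading_max, seed = seed))
}

#' Generate ordinal responses from a calibrated bank
#'
#' Simulees receive independent standard-normal primary and group traits
#' (bifactor orthogonality); each response is a categorical draw from the
#' model's category probabilities at the simulee's latent vector.
#'
#' @param bank calibrated [item_bank()] (e.g. from [gen_bank()]).
#' @param n_persons number of simulees.
#' @param seed integer seed.
#' @param latents optional list with `theta0` (length `n_persons`) and
#'   `theta_g` (`n_persons` x subdomains matrix) to reuse existing traits.
#' @return list with `responses` (integer matrix, persons x items), `theta0`,
#'   and `theta_g`.
#' @export
gen_responses <- function(bank, n_persons = 713, seed = 1L, latents = NULL) {
  validate_bank(bank, require_calibrated = TRUE)
  set.seed(seed)
  groups <- unique(bank$subdomain)
  if (is.null(latents)) {
    theta0 <- stats::rnorm(n_persons)
    theta_g <- matrix(stats::rnorm(n_persons * length(groups)),
                      n_persons, length(groups),
                      dimnames = list(NULL, groups))
  } else {
    theta0 <- latents$theta0
    theta_g <- latents$theta_g[, groups, drop = FALSE]
    n_persons <- length(theta0)
  }
  Y <- matrix(NA_integer_, n_persons, nrow(bank),
              dimnames = list(sprintf("p%04d", seq_len(n_persons)),
                              bank$item_id))
  for (j in seq_len(nrow(bank))) {
    tg <- theta_g[, bank$subdomain[j]]
    eta <- bank$a0[j] * theta0 + bank$ag[j] * tg
    cumge <- stats::plogis(outer(eta, bank$thresholds[[j]], `-`))
    u <- stats::runif(n_persons)
    Y[, j] <- as.integer(rowSums(u < cumge))
  }
  list(responses = Y, theta0 = theta0, theta_g = theta_g)
}

#' Generate criterion diagnoses from the primary trait
#'
#' Labels are Bernoulli with `P(D = 1 | theta0) = plogis(alpha +
#' beta * theta0)`; the intercept `alpha` is solved numerically so the
#' population-expected prevalence equals `prevalence_target`. The liability
#' runs through the primary trait only, the minimal structure supporting a
#' screener trained on a single criterion.
#'
#' @param theta0 numeric vector of primary traits (from [gen_responses()]).
#' @param prevalence_target expected prevalence in (0, 1); default 0.284.
#' @param signal_strength slope `beta` of the liability model; 0 gives labels
#'   independent of severity.
#' @param seed integer seed.
#' @return list with `labels` (integer 0/1), `alpha`, `beta`.
#' @export
gen_diagnosis <- function(theta0, prevalence_target = 0.284,
                          signal_strength = 2.5, seed = 1L) {
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("prevalence_target must be in (0, 1)")
  }
  gh <- gauss_hermite(61)
  expected_prev <- function(alpha) {
    sum(gh$weights * stats::plogis(alpha + signal_strength * gh$nodes)) -
      prevalence_target
  }
  alpha <- stats::uniroot(expected_prev, c(-50, 50))$root
  set.seed(seed)
  p <- stats::plogis(alpha + signal_strength * theta0)
  list(labels = as.integer(stats::runif(length(theta0)) < p),
       alpha = alpha, beta = signal_strength)
}
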