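#' CAT configuration
#'
#' Tuning parameters of the adaptive severity test.
#'
#' @param se_stop precision stopping threshold: the test stops once the score
#'   uncertainty (posterior SD mapped to the 0-100 reporting scale) falls to
#'   this value or below. Default 5 points on the 100-point scale.
#' @param min_items precision rule is not checked before this many items.
#' @param max_items hard cap on administered items (`Inf` = bank size).
#' @param remaining_info_stop second stopping rule: stop when no remaining
#'   item offers at least this much Fisher information at the current severity
#'   estimate.
#' @param top2_prob probability of administering the second-most informative
#'   item instead of the most informative one, to vary item content across
#'   sessions.
#' @param seed integer seed for the session-local randomization stream.
#' @param quad_points,group_quad_points quadrature sizes for EAP scoring.
#' @param marginal_info use prior-marginal item information (default) or
#'   information conditional on group factors at 0.
#' @return list of class `cat_config`.
#' @export
cat_config <- function(se_stop = 5, min_items = 4, max_items = Inf,
                       remaining_info_stop = 0.1, top2_prob = 0,
                       seed = 1L, quad_points = 49, group_quad_points = 21,
                       marginal_info = TRUE) {
  stopifnot(se_stop > 0, min_items >= 1, max_items >= min_items,
            top2_prob >= 0, top2_prob <= 1, remaining_info_stop >= 0)
  structure(list(se_stop = se_stop, min_items = as.integer(min_items),
                 max_items = max_items,
                 remaining_info_stop = remaining_info_stop,
                 top2_prob = top2_prob, seed = as.integer(seed),
                 quad_points = as.integer(quad_points),
                 group_quad_points = as.integer(group_quad_points),
                 marginal_info = isTRUE(marginal_info)),
            class = "cat_config")
}

#' Score transform from the latent scale to the 0-100 reporting scale
#'
#' Severity is reported as `center + scale * theta`, clipped to
#' `[lower, upper]`; the uncertainty is the posterior SD times `scale`
#' (scale factor only, no clipping). Defaults put the population mean at 50
#' with 15 points per latent SD, so the reachable latent range spans about
#' -3.3 to +3.3 SD.
#'
#' @param center,scale affine map parameters.
#' @param lower,upper clip bounds of the reporting scale.
#' @return list of class `score_transform`.
#' @export
score_transform <- function(center = 50, scale = 15, lower = 0, upper = 100) {
  stopifnot(scale > 0, lower < upper)
  structure(list(center = center, scale = scale, lower = lower, upper = upper),
            class = "score_transform")
}

#' Map latent values to reported scores
#' @param transform a [score_transform()].
#' @param theta latent value(s).
#' @return clipped score(s) in `[lower, upper]`.
#' @export
transform_score <- function(transform, theta) {
  pmin(pmax(transform$center + transform$scale * theta, transform$lower),
       transform$upper)
}

#' Map a posterior SD to the reporting scale
#' @param transform a [score_transform()].
#' @param se posterior SD(s) in latent units.
#' @return uncertainty on the reporting scale.
#' @export
transform_se <- function(transform, se) transform$scale * se

# session-local MINSTD stream: deterministic, independent of the global RNG
lcg_init <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  if (s <= 0) s <- s + 2147483646
  s
}
lcg_next <- function(state) {
  state <- (16807 * state) %% 2147483647
  list(u = state / 2147483647, state = state)
}

# cached flat representation of a bank for fast exact information lookups
info_context <- function(bank, marginal = TRUE, group_quad_points = 21) {
  nthr <- lengths(bank$thresholds)
  item_thr <- rep(seq_len(nrow(bank)), nthr)
  ncat <- nthr + 1L
  cat_item <- rep(seq_len(nrow(bank)), ncat)
  # category k of item j: p_k = cum_{k} - cum_{k+1}, cum_0 = 1, cum_K = 0
  first_thr <- cumsum(c(0L, nthr))[seq_len(nrow(bank))]
  left_idx <- unlist(lapply(seq_len(nrow(bank)), function(j) {
    c(0L, first_thr[j] + seq_len(nthr[j]))          # 0 = constant 1
  }))
  right_idx <- unlist(lapply(seq_len(nrow(bank)), function(j) {
    c(first_thr[j] + seq_len(nthr[j]), 0L)          # 0 = constant 0
  }))
  gh <- if (marginal) gauss_hermite(group_quad_points) else
    list(nodes = 0, weights = 1)
  list(a0 = bank$a0[item_thr], ag = bank$ag[item_thr],
       cv = unlist(bank$thresholds), a0_item = bank$a0,
       item_ids = bank$item_id, cat_item = cat_item,
       left = left_idx, right = right_idx, gh = gh, n_items = nrow(bank))
}

# exact per-item information at a single theta, for all items in the context
information_at <- function(ctx, theta) {
  n_ent <- length(ctx$cat_item)
  pbar <- numeric(n_ent)
  dbar <- numeric(n_ent)
  for (q in seq_along(ctx$gh$nodes)) {
    cum <- stats::plogis(ctx$a0 * theta + ctx$ag * ctx$gh$nodes[q] - ctx$cv)
    dcum <- ctx$a0 * cum * (1 - cum)
    cl <- ifelse(ctx$left == 0L, 1, cum[pmax(ctx$left, 1L)])
    cr <- ifelse(ctx$right == 0L, 0, cum[pmax(ctx$right, 1L)])
    dl <- ifelse(ctx$left == 0L, 0, dcum[pmax(ctx$left, 1L)])
    dr <- ifelse(ctx$right == 0L, 0, dcum[pmax(ctx$right, 1L)])
    w <- ctx$gh$weights[q]
    pbar <- pbar + w * (cl - cr)
    dbar <- dbar + w * (dl - dr)
  }
  info <- as.vector(rowsum(dbar^2 / pmax(pbar, 1e-300), ctx$cat_item))
  names(info) <- ctx$item_ids
  info
}

#' Select the next item to administer
#'
#' Ranks the unadministered items by Fisher information at the current
#' severity estimate. With probability `1 - top2_prob` the most informative
#' item is chosen, otherwise the runner-up; ties are broken by item id order.
#'
#' @param state list with `theta` (current EAP estimate), as from
#'   [eap_score()].
#' @param bank calibrated [item_bank()].
#' @param already_administered character vector of item ids to exclude.
#' @param config a [cat_config()].
#' @param u optional uniform deviate in `[0, 1)` driving the top-2 choice;
#'   sessions supply this from their own stream. Defaults to 0 (argmax) when
#'   `top2_prob` is 0, otherwise one draw from the global RNG.
#' @return the selected item id, or `NA_character_` with a warning if the
#'   bank is exhausted.
#' @export
next_item <- function(state, bank, already_administered = character(0),
                      config = cat_config(), u = NULL) {
  remaining <- setdiff(bank$item_id, already_administered)
  if (length(remaining) == 0L) {
    warning("bank exhausted: no item to administer")
    return(NA_character_)
  }
  sub <- bank[match(remaining, bank$item_id), , drop = FALSE]
  ctx <- info_context(sub, marginal = config$marginal_info,
                      group_quad_points = config$group_quad_points)
  info <- information_at(ctx, state$theta)
  ord <- order(-info, names(info))
  if (length(ord) == 1L || config$top2_prob == 0) return(names(info)[ord[1L]])
  if (is.null(u)) u <- stats::runif(1)
  pick <- if (u < config$top2_prob) 2L else 1L
  names(info)[ord[pick]]
}

#' Start a CAT session
#'
#' Initializes an adaptive session at the prior (severity estimate 0, SD 1 on
#' the latent scale) and selects the first item: the one offering maximum
#' information in the middle of the severity distribution.
#'
#' @param bank fully calibrated [item_bank()].
#' @param config a [cat_config()].
#' @param transform a [score_transform()].
#' @return object of class `cat_session` with the first item pending in
#'   `$pending_item`.
#' @export
start_session <- function(bank, config = cat_config(),
                          transform = score_transform()) {
  if (nrow(bank) == 0L) stop("cannot start a session on an empty bank")
  validate_bank(bank, require_calibrated = TRUE)
  gh0 <- gauss_hermite(config$quad_points)
  ghg <- gauss_hermite(config$group_quad_points)
  groups <- unique(bank$subdomain)
  group_ll <- stats::setNames(
    rep(list(matrix(0, length(gh0$nodes), length(ghg$nodes))), length(groups)),
    groups)
  ctx <- info_context(bank, marginal = config$marginal_info,
                      group_quad_points = config$group_quad_points)
  s <- structure(list(
    bank = bank, config = config, transform = transform,
    gh0 = gh0, ghg = ghg, info_ctx = ctx,
    group_ll = group_ll,
    administered = character(0),
    excluded = character(0),
    responses = integer(0),
    trajectory = data.frame(step = integer(0), item_id = character(0),
                            response = integer(0), score = numeric(0),
                            uncertainty = numeric(0),
                            stringsAsFactors = FALSE),
    state = list(theta = 0, se = 1),
    rng = lcg_init(config$seed),
    stopped = FALSE, stop_reason = NA_character_,
    pending_item = NA_character_
  ), class = "cat_session")
  select_into_session(s)
}

# pick the next item using the session's private stream
select_into_session <- function(s) {
  remaining <- setdiff(s$bank$item_id, c(s$administered, s$excluded))
  if (length(remaining) == 0L) {
    s$stopped <- TRUE; s$stop_reason <- "bank_exhausted"
    s$pending_item <- NA_character_
    return(s)
  }
  u <- NULL
  if (s$config$top2_prob > 0 && length(remaining) > 1L) {
    r <- lcg_next(s$rng); s$rng <- r$state; u <- r$u
  }
  info <- information_at(s$info_ctx, s$state$theta)
  info <- info[remaining]
  ord <- order(-info, names(info))
  pick <- 1L
  if (!is.null(u) && u < s$config$top2_prob && length(ord) > 1L) pick <- 2L
  s$pending_item <- names(info)[ord[pick]]
  s$administered <- c(s$administered, s$pending_item)
  s
}

session_rescore <- function(s) {
  Q0 <- length(s$gh0$nodes)
  total <- log(s$gh0$weights)
  for (g in names(s$group_ll)) {
    M <- s$group_ll[[g]]
    if (all(M == 0)) next
    shift <- apply(M, 1L, max)
    total <- total + shift +
      log(pmax(as.vector(exp(M - shift) %*% s$ghg$weights), 1e-300))
  }
  posterior_moments(s$gh0$nodes, total)
}

#' Record a response and advance the session
#'
#' Validates the response to the pending item, updates the EAP severity
#' estimate and its uncertainty over all responses so far, appends a step to
#' the 0-100-scale trajectory, evaluates the stopping rules and, if the
#' session continues, selects the next item.
#'
#' @param session a `cat_session`.
#' @param response 0-based ordinal code for the pending item.
#' @return the updated session; check `$stopped`, `$stop_reason`,
#'   `$pending_item`, `$trajectory`.
#' @export
update_session <- function(session, response) {
  s <- session
  if (s$stopped) stop("session already stopped (", s$stop_reason, ")")
  item <- s$pending_item
  j <- match(item, s$bank$item_id)
  K <- s$bank$n_categories[j]
  if (!is.numeric(response) || length(response) != 1L || is.na(response) ||
      response < 0 || response >= K || response != floor(response)) {
    stop("invalid response code for item '", item, "': expected 0..", K - 1L)
  }
  response <- as.integer(response)
  s$responses <- c(s$responses, stats::setNames(response, item))
  T0 <- rep(s$gh0$nodes, times = length(s$ghg$nodes))
  Tg <- rep(s$ghg$nodes, each = length(s$gh0$nodes))
  lp <- grm_log_probs(s$bank$a0[j], s$bank$ag[j], s$bank$thresholds[[j]],
                      T0, Tg)[, response + 1L]
  g <- s$bank$subdomain[j]
  s$group_ll[[g]] <- s$group_ll[[g]] +
    matrix(lp, length(s$gh0$nodes), length(s$ghg$nodes))
  s$state <- session_rescore(s)
  s$trajectory <- rbind(s$trajectory, data.frame(
    step = nrow(s$trajectory) + 1L, item_id = item, response = response,
    score = transform_score(s$transform, s$state$theta),
    uncertainty = transform_se(s$transform, s$state$se),
    stringsAsFactors = FALSE))
  st <- should_stop(s, s$bank, s$config)
  if (st$stop) {
    s$stopped <- TRUE; s$stop_reason <- st$reason
    s$pending_item <- NA_character_
    return(s)
  }
  select_into_session(s)
}

#' Evaluate the CAT stopping rules
#'
#' Rules, in order: precision (uncertainty on the reporting scale at or below
#' `se_stop`, only checked after `min_items` responses), remaining bank
#' information below `remaining_info_stop` at the current estimate, item
#' budget `max_items`, and bank exhaustion.
#'
#' @param session a `cat_session` with at least one recorded response.
#' @param bank the session's bank (kept explicit for scriptability).
#' @param config a [cat_config()].
#' @return list with `stop` (logical) and `reason` (one of `"precision"`,
#'   `"remaining_info"`, `"max_items"`, `"bank_exhausted"`, or `NA`).
#' @export
should_stop <- function(session, bank = session$bank,
                        config = session$config) {
  n <- length(session$responses)
  unc <- transform_se(session$transform, session$state$se)
  if (n >= config$min_items && unc <= config$se_stop) {
    return(list(stop = TRUE, reason = "precision"))
  }
  remaining <- setdiff(bank$item_id,
                       c(names(session$responses), session$excluded))
  if (length(remaining) == 0L) {
    return(list(stop = TRUE, reason = "bank_exhausted"))
  }
  if (n >= config$min_items && config$remaining_info_stop > 0) {
    info <- information_at(session$info_ctx, session$state$theta)[remaining]
    if (max(info) < config$remaining_info_stop) {
      return(list(stop = TRUE, reason = "remaining_info"))
    }
  }
  if (n >= config$max_items) {
    return(list(stop = TRUE, reason = "max_items"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Run one adaptive session against a response source
#'
#' @param bank calibrated [item_bank()].
#' @param responder function of an item id returning a 0-based code, or `NA`
#'   if that person has no stored response for the item.
#' @param config a [cat_config()].
#' @param transform a [score_transform()].
#' @param on_missing what to do when the responder returns `NA`: `"skip"`
#'   removes the item from this session's pool and selects again, `"error"`
#'   aborts.
#' @return a finished `cat_session`.
#' @export
run_cat <- function(bank, responder, config = cat_config(),
                    transform = score_transform(), on_missing = "skip") {
  s <- start_session(bank, config, transform)
  while (!s$stopped) {
    resp <- responder(s$pending_item)
    if (is.na(resp)) {
      if (on_missing == "error") {
        stop("no response available for item '", s$pending_item, "'")
      }
      # retract the selection, exclude the item, pick the next-best one
      s$excluded <- c(s$excluded, s$pending_item)
      s$administered <- setdiff(s$administered, s$pending_item)
      s <- select_into_session(s)
      next
    }
    s <- update_session(s, resp)
  }
  s
}

#' Batch EAP scores for a response matrix
#'
#' Full-bank posterior mean and SD of the primary trait for every row, using
#' the same marginalization over group factors as [eap_score()] but vectorized
#' over persons.
#'
#' @param responses integer matrix, persons x items (`NA` = missing).
#' @param bank calibrated [item_bank()].
#' @param quad_points,group_quad_points quadrature sizes.
#' @return data frame with `theta` and `se` per person.
#' @export
eap_scores <- function(responses, bank, quad_points = 49,
                       group_quad_points = 21) {
  validate_bank(bank, require_calibrated = TRUE)
  keep_cols <- intersect(colnames(responses), bank$item_id)
  if (!setequal(keep_cols, bank$item_id)) {
    stop("responses must cover every bank item")
  }
  responses <- responses[, keep_cols, drop = FALSE]
  validate_responses(responses, bank)
  responses <- responses[, bank$item_id, drop = FALSE]
  N <- nrow(responses)
  gh0 <- gauss_hermite(quad_points)
  ghg <- gauss_hermite(group_quad_points)
  Q0 <- length(gh0$nodes); Qg <- length(ghg$nodes)
  T0 <- rep(gh0$nodes, times = Qg)
  Tg <- rep(ghg$nodes, each = Q0)
  total <- matrix(log(gh0$weights), N, Q0, byrow = TRUE)
  for (g in unique(bank$subdomain)) {
    jj <- which(bank$subdomain == g)
    M <- matrix(0, N, Q0 * Qg)
    for (j in jj) {
      lpT <- t(grm_log_probs(bank$a0[j], bank$ag[j], bank$thresholds[[j]],
                             T0, Tg))
      oi <- which(!is.na(responses[, j]))
      M[oi, ] <- M[oi, ] + lpT[responses[oi, j] + 1L, , drop = FALSE]
    }
    shift <- matrixStats_rowMaxs(M)
    E <- exp(M - shift)
    Lsh <- E[, 1:Q0, drop = FALSE]
    if (Qg > 1L) {
      for (qg in 2:Qg) {
        Lsh <- Lsh + E[, ((qg - 1L) * Q0 + 1L):(qg * Q0), drop = FALSE] *
          (ghg$weights[qg] / ghg$weights[1L])
      }
    }
    total <- total + log(pmax(Lsh * ghg$weights[1L], 1e-300)) + shift
  }
  shiftA <- matrixStats_rowMaxs(total)
  W <- exp(total - shiftA)
  W <- W / rowSums(W)
  theta <- as.vector(W %*% gh0$nodes)
  v <- as.vector(W %*% gh0$nodes^2) - theta^2
  data.frame(theta = theta, se = sqrt(pmax(v, 1e-12)))
}

#' Simulate adaptive testing from complete response patterns
#'
#' Replays each person's stored responses through the adaptive engine: items
#' are selected adaptively and the person's recorded answer to each selected
#' item is fed back. Summarizes test length and the Pearson correlation of
#' the final CAT scores with full-bank EAP scores.
#'
#' @param full_responses integer matrix, persons x items; ideally complete.
#' @param bank calibrated [item_bank()].
#' @param config a [cat_config()]; each simulee's session seed is derived from
#'   `config$seed` plus the row number.
#' @param transform a [score_transform()].
#' @param on_missing `"skip"` (administer the next-best item) or `"drop"`
#'   (exclude the simulee from the summary), logged in the result.
#' @return list of class `cat_simulation`: `sessions`, and `summary` with
#'   `n`, `mean_items`, `range_items`, `r_full_bank`, plus per-person scores.
#' @export
run_simulated_cat <- function(full_responses, bank, config = cat_config(),
                              transform = score_transform(),
                              on_missing = c("skip", "drop")) {
  on_missing <- match.arg(on_missing)
  # columns for items outside the bank (e.g. filtered-out ones) are ignored
  keep_cols <- intersect(colnames(full_responses), bank$item_id)
  if (length(keep_cols) == 0L) stop("no response columns match the bank")
  full_responses <- full_responses[, keep_cols, drop = FALSE]
  validate_responses(full_responses, bank)
  N <- nrow(full_responses)
  sessions <- vector("list", N)
  dropped <- integer(0)
  for (i in seq_len(N)) {
    row <- full_responses[i, ]
    if (on_missing == "drop" && anyNA(row[bank$item_id])) {
      dropped <- c(dropped, i)
      next
    }
    cfg <- config
    cfg$seed <- (config$seed + i) %% 2147483646L + 1L
    responder <- function(item_id) row[[item_id]]
    sessions[[i]] <- run_cat(bank, responder, cfg, transform,
                             on_missing = "skip")
  }
  keep <- setdiff(seq_len(N), dropped)
  if (length(keep) == 0L) {
    return(structure(list(
      sessions = sessions, dropped = dropped,
      summary = list(n = 0L, mean_items = NA_real_,
                     range_items = c(NA_integer_, NA_integer_),
                     r_full_bank = NA_real_),
      cat_scores = numeric(0), full_scores = numeric(0)),
      class = "cat_simulation"))
  }
  n_items <- vapply(sessions[keep], function(s) length(s$responses), 0L)
  cat_scores <- vapply(sessions[keep], function(s) {
    transform_score(transform, s$state$theta)
  }, 0)
  full <- eap_scores(full_responses[keep, , drop = FALSE], bank,
                     quad_points = config$quad_points,
                     group_quad_points = config$group_quad_points)
  full_scores <- transform_score(transform, full$theta)
  r <- stats::cor(cat_scores, full_scores)
  structure(list(
    sessions = sessions,
    dropped = dropped,
    summary = list(n = length(keep), mean_items = mean(n_items),
                   range_items = range(n_items), r_full_bank = r),
    cat_scores = cat_scores, full_scores = full_scores),
    class = "cat_simulation")
}

#' Factory tuning grid
#'
#' The default simulated-CAT tuning search crosses four axes -- precision
#' stop, remaining-information stop, top-2 randomization probability, and the
#' item budget -- into 1200 candidate configurations.
#'
#' @return data frame with 1200 rows and columns `se_stop`,
#'   `remaining_info_stop`, `top2_prob`, `max_items`.
#' @export
default_tuning_grid <- function() {
  expand.grid(se_stop = c(4, 4.5, 5, 5.5, 6, 7),
              remaining_info_stop = c(0.05, 0.1, 0.2, 0.3, 0.5),
              top2_prob = c(0, 0.25, 0.5, 0.75, 1),
              max_items = c(10, 15, 20, 25, 30, 40, 50, 100),
              KEEP.OUT.ATTRS = FALSE)
}

#' Tuning search over CAT configurations
#'
#' Evaluates every grid row with [run_simulated_cat()] and selects, among the
#' configurations whose full-bank correlation is within `r_tol` of the grid
#' maximum, the one administering the fewest items on average (ties: first in
#' grid order).
#'
#' @param full_responses complete response matrix.
#' @param bank calibrated [item_bank()].
#' @param grid data frame of configuration columns accepted by
#'   [cat_config()]; see [default_tuning_grid()].
#' @param r_tol correlation tolerance defining the near-optimal set.
#' @param seed base seed shared by all evaluations (paired simulations).
#' @param transform a [score_transform()].
#' @return list with `best` (a [cat_config()]), `best_row` (grid index) and
#'   `frontier` (the grid with `mean_items` and `r_full_bank` appended).
#' @export
tune <- function(full_responses, bank, grid = default_tuning_grid(),
                 r_tol = 0.005, seed = 1L, transform = score_transform()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("empty tuning grid")
  frontier <- grid
  frontier$mean_items <- NA_real_
  frontier$r_full_bank <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- do.call(cat_config, c(as.list(grid[k, , drop = FALSE]),
                                 list(seed = seed)))
    sim <- run_simulated_cat(full_responses, bank, cfg, transform)
    frontier$mean_items[k] <- sim$summary$mean_items
    frontier$r_full_bank[k] <- sim$summary$r_full_bank
  }
  rmax <- max(frontier$r_full_bank)
  eligible <- which(frontier$r_full_bank >= rmax - r_tol)
  best_row <- eligible[which.min(frontier$mean_items[eligible])]
  best <- do.call(cat_config, c(as.list(grid[best_row, , drop = FALSE]),
                                list(seed = seed)))
  list(best = best, best_row = best_row, frontier = frontier)
}

#' Severity category thresholds
#'
#' Three ascending cut scores on the 0-100 scale separating none / mild /
#' moderate / severe. Defaults 35, 47, 60.
#'
#' @param t1,t2,t3 ascending cut scores within the reporting range.
#' @return numeric vector of class `severity_thresholds`.
#' @export
severity_thresholds <- function(t1 = 35, t2 = 47, t3 = 60) {
  v <- c(none_mild = t1, mild_moderate = t2, moderate_severe = t3)
  if (any(diff(v) <= 0)) stop("thresholds must be strictly ascending")
  if (any(v < 0 | v > 100)) stop("thresholds must lie in [0, 100]")
  structure(v, class = "severity_thresholds")
}

#' Classify a severity score
#'
#' Lower-inclusive binning: a score equal to a threshold enters the higher
#' category.
#'
#' @param score numeric score(s) in `[0, 100]`.
#' @param thresholds a [severity_thresholds()].
#' @return character vector over `{"none", "mild", "moderate", "severe"}`.
#' @export
classify_severity <- function(score, thresholds = severity_thresholds()) {
  if (any(is.na(score)) || any(score < 0 | score > 100)) {
    stop("scores must lie in [0, 100]")
  }
  labels <- c("none", "mild", "moderate", "severe")
  labels[findInterval(score, unclass(thresholds)) + 1L]
}

#' @export
print.cat_session <- function(x, ...) {
  cat("CAT session: ", length(x$responses), " item(s) administered",
      if (x$stopped) paste0(", stopped (", x$stop_reason, ")") else
        paste0(", pending '", x$pending_item, "'"), "\n", sep = "")
  if (nrow(x$trajectory)) {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf("  score %.2f, uncertainty %.2f\n", last$score,
                last$uncertainty))
  }
  invisible(x)
}

#' @export
print.cat_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Simulated CAT: n = %d, mean items %.2f (range %d-%d), r with full bank %.3f\n",
    s$n, s$mean_items, s$range_items[1], s$range_items[2], s$r_full_bank))
  invisible(x)
}
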