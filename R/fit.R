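#' Estimation options for item-bank calibration
#'
#' @param quad_points Gauss-Hermite nodes per latent dimension. The bifactor
#'   structure reduces every integral to two dimensions (primary x one group
#'   factor), so cost grows with `quad_points^2`, not with the number of
#'   subdomains.
#' @param tol relative change in marginal log-likelihood declaring convergence.
#' @param max_iter maximum EM cycles.
#' @param m_iter BFGS iterations per item per M-step (generalized EM: a few
#'   ascent steps per cycle keep the trace monotone at much lower cost than a
#'   full inner maximization).
#' @param verbose print the log-likelihood trace.
#' @return list of options.
#' @export
irt_options <- function(quad_points = 21, tol = 1e-5, max_iter = 500,
                        m_iter = 8, verbose = FALSE) {
  stopifnot(quad_points >= 2, tol > 0, max_iter >= 1, m_iter >= 1)
  list(quad_points = as.integer(quad_points), tol = tol,
       max_iter = as.integer(max_iter), m_iter = as.integer(m_iter),
       verbose = isTRUE(verbose))
}

# Collapse categories never observed in the data into the adjacent lower
# observed category (or the first observed one). Returns recoded responses,
# updated category counts, and the per-item code maps.
collapse_sparse_categories <- function(responses, bank) {
  maps <- vector("list", nrow(bank))
  names(maps) <- bank$item_id
  new_k <- bank$n_categories
  collapsed <- character(0)
  for (j in seq_len(nrow(bank))) {
    id <- bank$item_id[j]
    y <- responses[, id]
    K <- bank$n_categories[j]
    counts <- tabulate(y + 1L, nbins = K)
    observed <- which(counts > 0L) - 1L
    if (length(observed) < 2L) {
      stop("item '", id, "' has fewer than 2 observed categories")
    }
    if (length(observed) < K) {
      map <- pmax(vapply(0:(K - 1L), function(code) sum(observed <= code), 0L) - 1L, 0L)
      responses[, id] <- map[y + 1L]
      maps[[j]] <- map
      new_k[j] <- length(observed)
      collapsed <- c(collapsed, id)
    }
  }
  if (length(collapsed)) {
    warning("collapsed unobserved categories for item(s): ",
            paste(collapsed, collapse = ", "))
  }
  list(responses = responses, n_categories = new_k, maps = maps)
}

# Cheap order-sensitive fingerprint of a response matrix, used to refuse
# likelihood-ratio tests across different data sets.
data_fingerprint <- function(responses) {
  y <- responses
  y[is.na(y)] <- -1L
  v <- as.vector(y)
  c(nrow(responses), ncol(responses), sum(v),
    sum(v * seq_along(v) %% 97), sum(v^2))
}

# Shared EM engine. `free_ag = FALSE` pins every group slope at zero and the
# group dimension collapses to a single quadrature node, giving the
# unidimensional graded model.
fit_graded_em <- function(responses, bank, options, free_ag, model_tag) {
  validate_bank(bank)
  validate_responses(responses, bank)
  responses <- responses[, bank$item_id, drop = FALSE]
  cs <- collapse_sparse_categories(responses, bank)
  responses <- cs$responses
  n_cat <- cs$n_categories
  N <- nrow(responses)
  n_items <- nrow(bank)
  if (n_items < 2L) stop("need at least 2 items to calibrate")

  groups <- split(seq_len(n_items), bank$subdomain)
  if (length(groups) < 2L && free_ag) {
    # one subdomain: the group factor is confounded with the primary
    # dimension, so its slopes are unidentifiable and pinned at 0
    free_ag <- FALSE
  }

  gh0 <- gauss_hermite(options$quad_points)
  if (free_ag) {
    ghg <- gauss_hermite(options$quad_points)
  } else {
    ghg <- list(nodes = 0, weights = 1)
  }
  Q0 <- length(gh0$nodes); Qg <- length(ghg$nodes)
  # grid index m = (qg - 1) * Q0 + q0; theta0 varies fastest
  T0 <- rep(gh0$nodes, times = Qg)
  Tg <- rep(ghg$nodes, each = Q0)
  log_w0 <- log(gh0$weights)
  log_wg_grid <- rep(log(ghg$weights), each = Q0)

  # start values: unit primary slope, thresholds from marginal proportions
  a0 <- rep(1, n_items)
  ag <- if (free_ag) rep(0.5, n_items) else rep(0, n_items)
  thr <- vector("list", n_items)
  for (j in seq_len(n_items)) {
    y <- responses[, j]
    K <- n_cat[j]
    pge <- vapply(1:(K - 1L), function(k) mean(y >= k, na.rm = TRUE), 0)
    pge <- pmin(pmax(pge, 1 / (2 * N)), 1 - 1 / (2 * N))
    cv <- -stats::qlogis(pge)
    thr[[j]] <- cv + cumsum(c(0, pmax(diff(cv), 0.05) - diff(cv)))
  }

  obs_idx <- lapply(seq_len(n_items), function(j) which(!is.na(responses[, j])))

  loglik_trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    # ---- E step ----------------------------------------------------------
    logLg <- vector("list", length(groups))   # N x Q0 per group
    Mg <- vector("list", length(groups))      # N x (Q0*Qg) per group
    for (g in seq_along(groups)) {
      M <- matrix(0, N, Q0 * Qg)
      for (j in groups[[g]]) {
        lpT <- t(grm_log_probs(a0[j], ag[j], thr[[j]], T0, Tg))  # K x grid
        oi <- obs_idx[[j]]
        M[oi, ] <- M[oi, ] + lpT[responses[oi, j] + 1L, , drop = FALSE]
      }
      Mg[[g]] <- M
      shift <- matrixStats_rowMaxs(M)
      E <- exp(M - shift) * rep(exp(log_wg_grid - max(log_wg_grid)), each = N)
      Lsh <- E[, 1:Q0, drop = FALSE]
      if (Qg > 1L) {
        for (qg in 2:Qg) {
          Lsh <- Lsh + E[, ((qg - 1L) * Q0 + 1L):(qg * Q0), drop = FALSE]
        }
      }
      logLg[[g]] <- log(pmax(Lsh, 1e-300)) + shift + max(log_wg_grid)
    }
    logA <- matrix(log_w0, N, Q0, byrow = TRUE)
    for (g in seq_along(groups)) logA <- logA + logLg[[g]]
    shiftA <- matrixStats_rowMaxs(logA)
    person_ll <- shiftA + log(rowSums(exp(logA - shiftA)))
    new_loglik <- sum(person_ll)
    loglik_trace <- c(loglik_trace, new_loglik)
    if (options$verbose) {
      message(sprintf("EM iter %d: loglik %.6f", iter, new_loglik))
    }
    rel <- abs(new_loglik - loglik) / (abs(loglik) + 1e-10)
    loglik <- new_loglik
    if (iter > 1L && rel < options$tol) { converged <- TRUE; break }
    if (iter >= options$max_iter) break

    # ---- expected counts + M step ---------------------------------------
    for (g in seq_along(groups)) {
      # posterior over (q0, qg) pairs for this group
      logpost <- (logA - logLg[[g]] - person_ll)[, rep(1:Q0, Qg)] +
        matrix(log_wg_grid, N, Q0 * Qg, byrow = TRUE) + Mg[[g]]
      post <- exp(logpost)
      for (j in groups[[g]]) {
        oi <- obs_idx[[j]]
        r <- rowsum(post[oi, , drop = FALSE], responses[oi, j],
                    reorder = TRUE)
        # rowsum drops absent categories; after collapse all are present
        upd <- mstep_item(r, a0[j], ag[j], thr[[j]], T0, Tg,
                          free_ag = free_ag, maxit = options$m_iter)
        a0[j] <- upd$a0; ag[j] <- upd$ag; thr[[j]] <- upd$thresholds
      }
    }
  }

  # sign conventions: reflect the primary dimension if predominantly
  # negative, then each group factor independently
  if (sum(a0) < 0) a0 <- -a0
  for (g in seq_along(groups)) {
    jj <- groups[[g]]
    if (sum(ag[jj]) < 0) ag[jj] <- -ag[jj]
  }

  out_bank <- bank
  out_bank$n_categories <- n_cat
  out_bank$a0 <- a0
  out_bank$ag <- ag
  out_bank$thresholds <- thr
  lam <- standardized_loadings(a0, ag)
  res <- list(
    bank = out_bank,
    loadings = data.frame(item_id = bank$item_id,
                          subdomain = bank$subdomain,
                          lambda0 = lam$lambda0, lambdag = lam$lambdag,
                          stringsAsFactors = FALSE),
    loglik = loglik,
    loglik_trace = loglik_trace,
    iterations = iter,
    converged = converged,
    model = model_tag,
    n_persons = N,
    n_free_group_slopes = if (free_ag) n_items else 0L,
    category_maps = cs$maps,
    fingerprint = data_fingerprint(responses),
    options = options
  )
  class(res) <- "calibration_result"
  if (!converged) {
    warning("EM did not converge in ", options$max_iter,
            " iterations (model ", model_tag, ")")
  }
  res
}

matrixStats_rowMaxs <- function(m) {
  do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
}

# One-item M step: a few BFGS steps on the expected complete-data
# log-likelihood, thresholds kept ordered via a log-difference
# reparameterization. Analytic gradient.
mstep_item <- function(r, a0, ag, thresholds, T0, Tg, free_ag, maxit) {
  K <- nrow(r)
  tpar <- c(thresholds[1L], if (K > 2L) log(diff(thresholds)))
  par <- if (free_ag) c(a0, ag, tpar) else c(a0, tpar)

  unpack <- function(par) {
    if (free_ag) {
      list(a0 = par[1L], ag = par[2L],
           cv = cumsum(c(par[3L], if (K > 2L) exp(par[4:(K + 1L)]))))
    } else {
      list(a0 = par[1L], ag = ag,
           cv = cumsum(c(par[2L], if (K > 2L) exp(par[3:K]))))
    }
  }
  negQ <- function(par) {
    p <- unpack(par)
    lp <- grm_log_probs(p$a0, p$ag, p$cv, T0, Tg)
    -sum(t(r) * lp)
  }
  negQ_grad <- function(par) {
    p <- unpack(par)
    eta <- p$a0 * T0 + p$ag * Tg
    cum <- stats::plogis(outer(eta, p$cv, `-`))        # M x (K-1)
    pr <- cbind(1, cum) - cbind(cum, 0)                # M x K category probs
    pr <- pmax(pr, 1e-300)
    ratio <- t(r) / pr                                 # M x K
    dcum <- cum * (1 - cum)
    # d p_k / d eta = dcum_k - dcum_{k+1} with virtual zeros at ends
    dp_deta <- cbind(0, dcum) - cbind(dcum, 0)
    dQ_deta <- rowSums(ratio * dp_deta)
    g_a0 <- sum(T0 * dQ_deta)
    g_ag <- sum(Tg * dQ_deta)
    # d Q / d c_k, k = 1..K-1 (c_k separates 0-based categories k-1 and k)
    g_c <- vapply(seq_len(K - 1L), function(k) {
      sum(dcum[, k] * (ratio[, k] - ratio[, k + 1L]))
    }, 0)
    # chain rule through c_k = t_1 + sum_{j<=k} exp(t_j)
    off <- if (free_ag) 2L else 1L
    g_t <- numeric(K - 1L)
    g_t[1L] <- sum(g_c)
    if (K > 2L) {
      for (k in 2:(K - 1L)) {
        g_t[k] <- exp(par[off + k]) * sum(g_c[k:(K - 1L)])
      }
    }
    g <- if (free_ag) c(g_a0, g_ag, g_t) else c(g_a0, g_t)
    -g
  }
  fit <- stats::optim(par, negQ, negQ_grad, method = "BFGS",
                      control = list(maxit = maxit))
  p <- unpack(fit$par)
  list(a0 = p$a0, ag = p$ag, thresholds = p$cv)
}

#' Calibrate an item bank under the bifactor graded-response model
#'
#' Fits the logistic graded model in which every item loads on the primary
#' severity dimension and on exactly one group (subdomain) factor, all factors
#' independent standard normal. Marginal maximum likelihood via EM with
#' Gauss-Hermite quadrature; the bifactor restriction reduces every person's
#' likelihood to two-dimensional integrals per subdomain regardless of how
#' many subdomains the bank has.
#'
#' Categories never observed in the data are collapsed into the adjacent
#' observed category with a warning; an item with fewer than two observed
#' categories is rejected by name. The primary dimension's sign is fixed by
#' reflection (slopes predominantly nonnegative). With a single subdomain the
#' group slopes are unidentifiable and pinned at zero.
#'
#' @param responses integer matrix, persons x items, codes `0..k-1`, `NA`
#'   missing.
#' @param bank an [item_bank()]; parameters present in it are ignored and
#'   refitted.
#' @param options an [irt_options()] list.
#' @return object of class `calibration_result`: the calibrated bank,
#'   standardized loadings, marginal log-likelihood and its (nondecreasing)
#'   EM trace, iteration count, convergence flag, and model tag.
#' @seealso [fit_unidimensional()], [lr_test()], [filter_items()]
#' @export
fit_bifactor <- function(responses, bank, options = irt_options()) {
  fit_graded_em(responses, bank, options, free_ag = TRUE,
                model_tag = "bifactor")
}

#' Calibrate the unidimensional graded-response model
#'
#' Identical model and estimation as [fit_bifactor()] with every group slope
#' fixed at zero: the nested unidimensional alternative used by the
#' likelihood-ratio comparison.
#'
#' @inheritParams fit_bifactor
#' @return a `calibration_result` with model tag `"unidimensional"`.
#' @export
fit_unidimensional <- function(responses, bank, options = irt_options()) {
  fit_graded_em(responses, bank, options, free_ag = FALSE,
                model_tag = "unidimensional")
}

#' Likelihood-ratio test between nested calibrations
#'
#' Compares a bifactor fit against the unidimensional fit of the same data:
#' `chi2 = 2 * (loglik_full - loglik_reduced)` on degrees of freedom equal to
#' the number of group slopes freed in the full model (one per item).
#'
#' @param full the richer `calibration_result` (typically bifactor).
#' @param reduced the nested `calibration_result` (typically unidimensional).
#' @return list with `chi2`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "calibration_result"),
            inherits(reduced, "calibration_result"))
  if (!isTRUE(all.equal(full$fingerprint, reduced$fingerprint))) {
    stop("calibrations were fitted to different data")
  }
  df <- full$n_free_group_slopes - reduced$n_free_group_slopes
  if (df < 0L) stop("'reduced' has more free parameters than 'full'")
  chi2 <- max(2 * (full$loglik - reduced$loglik), 0)
  p <- if (df == 0L) {
    if (chi2 > 0) 0 else 1
  } else {
    stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p = p)
}

#' Remove poorly discriminating items
#'
#' Drops every item whose standardized primary loading falls below
#' `min_loading` (default 0.3), the conventional cut for an item that
#' contributes too little discrimination on the target dimension to be worth
#' administering.
#'
#' @param calib a `calibration_result`.
#' @param min_loading loading threshold; items with `lambda0 < min_loading`
#'   are removed.
#' @return list with `bank` (calibrated retained bank), `removed` (data frame
#'   of removed item ids and their loadings) and `min_loading`.
#' @export
filter_items <- function(calib, min_loading = 0.3) {
  stopifnot(inherits(calib, "calibration_result"))
  lam <- calib$loadings
  drop <- lam$lambda0 < min_loading
  if (all(drop)) stop("filter removed every item in the bank")
  bank <- calib$bank[!drop, , drop = FALSE]
  class(bank) <- c("item_bank", "data.frame")
  list(bank = bank,
       removed = data.frame(item_id = lam$item_id[drop],
                            lambda0 = lam$lambda0[drop],
                            stringsAsFactors = FALSE),
       min_loading = min_loading)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Graded-response calibration (", x$model, ")\n", sep = "")
  cat("  items: ", nrow(x$bank), ", persons: ", x$n_persons, "\n", sep = "")
  cat("  loglik: ", format(x$loglik), " after ", x$iterations,
      " EM iterations (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  invisible(x)
}
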