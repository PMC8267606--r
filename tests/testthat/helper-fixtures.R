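# Fixtures are built in code with fixed seeds; heavyweight ones are memoised
# so several test files (and the acceptance suite) share one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# two correlated binary items in one subdomain: small enough for brute force
toy_binary_bank <- function() {
  item_bank(c("x1", "x2"), c("g", "g"), c(2L, 2L),
            a0 = c(1.2, 0.8), ag = c(0.6, 0.9),
            thresholds = list(0.3, -0.4))
}

# 6 graded items, 2 subdomains: smallest bank where the bifactor matters
toy_graded <- function() {
  memo("toy_graded", {
    gb <- gen_bank(n_items = 6, subdomain_sizes = c(a = 3, b = 3),
                   category_mix = 0, seed = 3)
    gr <- gen_responses(gb$bank, n_persons = 200, seed = 4)
    list(bank = gb$bank, truth = gb$truth, responses = gr$responses,
         theta0 = gr$theta0)
  })
}

toy_graded_fits <- function() {
  memo("toy_graded_fits", {
    d <- toy_graded()
    opts <- irt_options(quad_points = 11, max_iter = 100)
    list(bi = suppressWarnings(fit_bifactor(d$responses, d$bank, opts)),
         uni = suppressWarnings(fit_unidimensional(d$responses, d$bank, opts)))
  })
}

# mid-sized calibrated world for CAT / CAD / evaluation tests
midi_world <- function() {
  memo("midi_world", {
    gb <- gen_bank(n_items = 40,
                   subdomain_sizes = c(a = 8, b = 8, c = 8, d = 8, e = 8),
                   seed = 21)
    gr <- gen_responses(gb$bank, n_persons = 400, seed = 22)
    gd <- gen_diagnosis(gr$theta0, seed = 23)
    list(bank = gb$bank, truth = gb$truth, responses = gr$responses,
         theta0 = gr$theta0, labels = gd$labels)
  })
}

# packaged high-information fixture bank (plain-text, shipped in extdata)
fixture_bank <- function() {
  read_bank(system.file("extdata", "fixture_bank.tsv", package = "catcad"))
}

# dense-grid EAP oracle: trapezoid integration over theta0 with the group
# factors integrated out on a fine inner grid; independent of eap_score()
eap_oracle <- function(responses, bank, n_grid = 2001, span = 8) {
  g <- seq(-span, span, length.out = n_grid)
  gg <- seq(-span, span, length.out = 401)
  wg <- stats::dnorm(gg); wg <- wg / sum(wg)
  logpost <- stats::dnorm(g, log = TRUE)
  for (sd_g in unique(bank$subdomain)) {
    ids <- intersect(names(responses), bank$item_id[bank$subdomain == sd_g])
    if (!length(ids)) next
    inner <- matrix(0, n_grid, length(gg))
    for (id in ids) {
      j <- match(id, bank$item_id)
      p <- grm_probs(bank$a0[j], bank$ag[j], bank$thresholds[[j]],
                     theta0 = rep(g, times = length(gg)),
                     thetag = rep(gg, each = n_grid))
      inner <- inner + log(matrix(p[, responses[[id]] + 1L], n_grid,
                                  length(gg)))
    }
    logpost <- logpost + log(as.vector(exp(inner) %*% wg))
  }
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  m <- sum(w * g)
  list(theta = m, se = sqrt(sum(w * (g - m)^2)))
}

# full-scale recovery world: 211 items (8 planted poor), 713 simulees;
# shared by the filter-recovery and loading-recovery acceptance criteria.
# Quadrature reduced to 11 points per dimension to stay inside the test
# budget (recovery is insensitive to this; see the methods vignette).
big_recovery <- function() {
  memo("big_recovery", {
    gb <- gen_bank(n_items = 211, n_poor_items = 8, seed = 11)
    gr <- gen_responses(gb$bank, n_persons = 713, seed = 12)
    fit <- suppressWarnings(
      fit_bifactor(gr$responses, gb$bank,
                   irt_options(quad_points = 11, max_iter = 200)))
    list(truth = gb$truth, fit = fit)
  })
}

# simulated-CAT fidelity world: 203 informative items, 700 simulees
t3_simulation <- function() {
  memo("t3_simulation", {
    sizes <- c(exposure = 5, mood_cognition = 56, arousal_reactivity = 76,
               avoidance = 17, intrusion = 49)
    gb <- gen_bank(n_items = 203, subdomain_sizes = sizes, seed = 101)
    gr <- gen_responses(gb$bank, n_persons = 700, seed = 102)
    sim <- run_simulated_cat(gr$responses, gb$bank,
                             cat_config(se_stop = 5, seed = 103))
    list(bank = gb$bank, sim = sim)
  })
}

# marginal probability of a full response pattern (same grids as eap_oracle)
pattern_prob <- function(responses, bank, n_grid = 801, span = 8) {
  g <- seq(-span, span, length.out = n_grid)
  gg <- seq(-span, span, length.out = 201)
  wg <- stats::dnorm(gg); wg <- wg / sum(wg)
  w0 <- stats::dnorm(g); w0 <- w0 / sum(w0)
  like <- rep(1, n_grid)
  for (sd_g in unique(bank$subdomain)) {
    ids <- intersect(names(responses), bank$item_id[bank$subdomain == sd_g])
    if (!length(ids)) next
    inner <- matrix(0, n_grid, length(gg))
    for (id in ids) {
      j <- match(id, bank$item_id)
      p <- grm_probs(bank$a0[j], bank$ag[j], bank$thresholds[[j]],
                     theta0 = rep(g, times = length(gg)),
                     thetag = rep(gg, each = n_grid))
      inner <- inner + log(matrix(p[, responses[[id]] + 1L], n_grid,
                                  length(gg)))
    }
    like <- like * as.vector(exp(inner) %*% wg)
  }
  sum(w0 * like)
}
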