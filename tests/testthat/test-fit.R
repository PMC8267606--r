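# brute-force marginal log-likelihood by dense two-dimensional integration,
# independent of the EM engine's quadrature bookkeeping
dense_marginal_loglik <- function(bank, Y, n_grid = 201, span = 7) {
  g <- seq(-span, span, length.out = n_grid)
  w <- stats::dnorm(g); w <- w / sum(w)
  W <- outer(w, w)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    M <- matrix(0, n_grid, n_grid)
    for (j in seq_len(nrow(bank))) {
      if (is.na(Y[i, j])) next
      p <- grm_probs(bank$a0[j], bank$ag[j], bank$thresholds[[j]],
                     theta0 = rep(g, times = n_grid),
                     thetag = rep(g, each = n_grid))
      M <- M + log(matrix(p[, Y[i, j] + 1L], n_grid, n_grid))
    }
    ll <- ll + log(sum(exp(M) * W))
  }
  ll
}

test_that("fitted marginal log-likelihood matches the dense-grid oracle", {
  bank <- toy_binary_bank()
  gr <- gen_responses(bank, n_persons = 200, seed = 5)
  fit <- fit_bifactor(gr$responses, bank,
                      irt_options(quad_points = 31, max_iter = 150))
  oracle <- dense_marginal_loglik(fit$bank, gr$responses, n_grid = 401)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
  # also the closed pattern-sum: 4 patterns for 2 binary items
  pats <- expand.grid(0:1, 0:1)
  counts <- table(factor(paste(gr$responses[, 1], gr$responses[, 2]),
                         levels = paste(pats[, 1], pats[, 2])))
  pat_ll <- vapply(seq_len(4), function(r) {
    dense_marginal_loglik(fit$bank,
                          matrix(as.integer(pats[r, ]), 1, 2,
                                 dimnames = list(NULL, bank$item_id)),
                          n_grid = 401)
  }, 0)
  expect_equal(fit$loglik, sum(as.numeric(counts) * pat_ll), tolerance = 1e-6)
})

test_that("EM trace is nondecreasing and the models nest", {
  fits <- toy_graded_fits()
  expect_true(all(diff(fits$bi$loglik_trace) >= -1e-6))
  expect_true(all(diff(fits$uni$loglik_trace) >= -1e-6))
  expect_gte(fits$bi$loglik, fits$uni$loglik)
  expect_true(fits$bi$converged)
  expect_true(all(abs(fits$bi$loadings$lambda0) <= 1))
  expect_true(all(abs(fits$bi$loadings$lambdag) <= 1))
})

test_that("single-subdomain bifactor pins group slopes and agrees with unidimensional", {
  gb <- gen_bank(n_items = 5, subdomain_sizes = c(only = 5),
                 category_mix = 0, group_loading_range = c(0, 0.01), seed = 13)
  gr <- gen_responses(gb$bank, n_persons = 250, seed = 14)
  opts <- irt_options(quad_points = 15, max_iter = 150)
  bi <- fit_bifactor(gr$responses, gb$bank, opts)
  uni <- fit_unidimensional(gr$responses, gb$bank, opts)
  expect_identical(bi$n_free_group_slopes, 0L)
  expect_equal(bi$bank$ag, rep(0, 5))
  expect_equal(bi$bank$a0, uni$bank$a0, tolerance = 1e-4)
  expect_equal(bi$loglik, uni$loglik, tolerance = 1e-7)
})

test_that("unobserved categories are collapsed, sparse items rejected", {
  bank <- item_bank(c("a", "b"), c("s", "s"), c(4, 4))
  set.seed(8)
  y <- cbind(a = sample(c(0L, 1L, 3L), 120, replace = TRUE),  # 2 never seen
             b = sample(0:3, 120, replace = TRUE))
  w <- testthat::capture_warnings(
    fit <- fit_unidimensional(y, bank, irt_options(quad_points = 9,
                                                   max_iter = 40)))
  expect_true(any(grepl("collapsed unobserved categories.*a", w)))
  expect_identical(fit$bank$n_categories, c(3L, 4L))
  y_const <- cbind(a = rep(2L, 50), b = sample(0:3, 50, replace = TRUE))
  expect_error(
    suppressWarnings(fit_unidimensional(y_const, bank,
                                        irt_options(max_iter = 5))),
    "'a'.*fewer than 2")
})

test_that("lr_test follows the nested-model conventions", {
  fits <- toy_graded_fits()
  lrt <- lr_test(fits$bi, fits$uni)
  expect_gte(lrt$chi2, 0)
  # df = one freed group slope per item
  expect_identical(lrt$df, nrow(fits$bi$bank))
  expect_equal(lrt$chi2, 2 * (fits$bi$loglik - fits$uni$loglik))
  # identical fits give chi2 = 0, p = 1
  self <- lr_test(fits$bi, fits$bi)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  # refuses different data
  other <- toy_graded()
  fake <- fits$uni
  fake$fingerprint <- fake$fingerprint + 1
  expect_error(lr_test(fits$bi, fake), "different data")
})

test_that("loading filter removes what it should and reports it", {
  fits <- toy_graded_fits()
  all_kept <- filter_items(fits$bi, min_loading = 0)
  expect_identical(nrow(all_kept$bank), nrow(fits$bi$bank))
  expect_identical(nrow(all_kept$removed), 0L)
  expect_error(filter_items(fits$bi, min_loading = 1.01), "every item")
  cut <- 0.5
  fl <- filter_items(fits$bi, min_loading = cut)
  expect_setequal(fl$removed$item_id,
                  fits$bi$loadings$item_id[fits$bi$loadings$lambda0 < cut])
  expect_true(all(fl$removed$lambda0 < cut))
})

test_that("group slopes shrink and LR stays small when the truth is unidimensional", {
  # generate from ag = 0 truth; bifactor should not claim group structure
  gb <- gen_bank(n_items = 12, subdomain_sizes = c(a = 6, b = 6),
                 category_mix = 0, group_loading_range = c(0, 1e-6),
                 seed = 31)
  opts <- irt_options(quad_points = 9, max_iter = 80)
  hits <- 0L; reps <- 3L
  for (r in seq_len(reps)) {
    gr <- gen_responses(gb$bank, n_persons = 300, seed = 40 + r)
    bi <- suppressWarnings(fit_bifactor(gr$responses, gb$bank, opts))
    uni <- suppressWarnings(fit_unidimensional(gr$responses, gb$bank, opts))
    lrt <- lr_test(bi, uni)
    # group loadings are weakly identified at this n; "shrink toward 0"
    # means well below the informative-range floor of 0.45
    expect_lt(mean(abs(bi$loadings$lambdag)), 0.35)
    if (lrt$chi2 < stats::qchisq(0.95, df = lrt$df)) hits <- hits + 1L
  }
  expect_gte(hits, reps - 1L)  # allow one near-threshold replicate
})
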