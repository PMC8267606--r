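test_that("next_item follows the max-information rule", {
  w <- midi_world()
  bank <- w$bank
  state <- list(theta = 0.4, se = 0.8)
  # exhaustive-scan oracle over a <= 20 item sub-bank
  sub <- bank[1:18, ]
  class(sub) <- c("item_bank", "data.frame")
  info <- item_information(sub, state$theta)[, 1]
  oracle_best <- names(sort(-info))[1]
  expect_identical(next_item(state, sub, config = cat_config(top2_prob = 0)),
                   oracle_best)
  # runner-up with top2_prob = 1
  oracle_second <- names(sort(-info))[2]
  expect_identical(
    next_item(state, sub, config = cat_config(top2_prob = 1), u = 0.3),
    oracle_second)
  # forced choice with one remaining item
  last <- sub$item_id[5]
  expect_identical(
    next_item(state, sub, setdiff(sub$item_id, last), cat_config()), last)
  # exhausted bank signals
  expect_warning(out <- next_item(state, sub, sub$item_id, cat_config()),
                 "exhausted")
  expect_true(is.na(out))
})

test_that("session start picks the informative middle item deterministically", {
  bank <- item_bank(c("hi", "lo"), c("g", "g"), c(2L, 2L),
                    a0 = c(2, 0.8), ag = c(0, 0), thresholds = list(0, 0))
  s <- start_session(bank)
  expect_identical(s$pending_item, "hi")
  expect_error(start_session(bank[0, ]), "empty bank")
  expect_error(start_session(item_bank("u", "g", 4L)), "not calibrated")
  w <- midi_world()
  s1 <- start_session(w$bank, cat_config(top2_prob = 0.5, seed = 7))
  s2 <- start_session(w$bank, cat_config(top2_prob = 0.5, seed = 7))
  expect_identical(s1$pending_item, s2$pending_item)
})

test_that("update_session validates codes and moves the score the right way", {
  w <- midi_world()
  s <- start_session(w$bank)
  j <- match(s$pending_item, w$bank$item_id)
  expect_error(update_session(s, w$bank$n_categories[j]),
               paste0("'", s$pending_item, "'"))
  s0 <- update_session(s, 0)      # lowest category: score drops below 50
  expect_lt(s0$trajectory$score[1], 50)
  sK <- update_session(s, w$bank$n_categories[j] - 1L)
  expect_gt(sK$trajectory$score[1], 50)
})

test_that("sessions are reproducible and never repeat an item", {
  w <- midi_world()
  cfg <- cat_config(se_stop = 5, top2_prob = 0.5, seed = 11, max_items = 20)
  run_one <- function() {
    run_cat(w$bank, function(id) w$responses[7, id], cfg)
  }
  a <- run_one(); b <- run_one()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$stop_reason, b$stop_reason)
  expect_false(anyDuplicated(a$administered) > 0)
})

test_that("stop rules fire in the documented order with recorded reasons", {
  fb <- fixture_bank()
  gr <- gen_responses(fb, n_persons = 4, seed = 778)
  # precision stop: uncertainty at or below 5 when it says so
  s <- run_cat(fb, function(id) gr$responses[1, id], cat_config(se_stop = 5))
  expect_identical(s$stop_reason, "precision")
  expect_lte(s$trajectory$uncertainty[nrow(s$trajectory)], 5)
  expect_gte(length(s$responses), 4)          # min_items honored
  # uncertainty after one strong item stays far above the threshold
  expect_gt(s$trajectory$uncertainty[1], 5)
  # max_items cap
  s2 <- run_cat(fb, function(id) gr$responses[1, id],
                cat_config(se_stop = 0.01, max_items = 6,
                           remaining_info_stop = 0))
  expect_identical(s2$stop_reason, "max_items")
  expect_identical(length(s2$responses), 6L)
  # bank exhaustion when nothing else can stop it
  small <- fb[1:5, ]; class(small) <- c("item_bank", "data.frame")
  s3 <- run_cat(small, function(id) gr$responses[1, id],
                cat_config(se_stop = 0.01, remaining_info_stop = 0))
  expect_identical(s3$stop_reason, "bank_exhausted")
  expect_identical(length(s3$responses), 5L)
})

test_that("12-step fixture session has nonincreasing uncertainty", {
  fb <- fixture_bank()
  gr <- gen_responses(fb, n_persons = 30, seed = 778)
  s <- run_cat(fb, function(id) gr$responses[5, id], cat_config(se_stop = 5))
  expect_identical(nrow(s$trajectory), 12L)
  expect_true(all(diff(s$trajectory$uncertainty) <= 0))
  expect_identical(s$stop_reason, "precision")
})

test_that("unlimited budget reproduces full-bank EAP scores", {
  w <- midi_world()
  sub <- w$responses[1:6, ]
  sim <- run_simulated_cat(sub, w$bank,
                           cat_config(se_stop = 1e-6, remaining_info_stop = 0,
                                      min_items = 1))
  expect_true(all(vapply(sim$sessions, function(s) length(s$responses), 0L) ==
                    nrow(w$bank)))
  expect_equal(sim$cat_scores, sim$full_scores, tolerance = 1e-10)
  expect_equal(sim$summary$r_full_bank, 1, tolerance = 1e-10)
})

test_that("raising se_stop never lengthens the paired simulated test", {
  w <- midi_world()
  sub <- w$responses[1:25, ]
  mean_items <- vapply(c(4, 8, 16), function(ss) {
    run_simulated_cat(sub, w$bank,
                      cat_config(se_stop = ss, seed = 5))$summary$mean_items
  }, 0)
  expect_true(all(diff(mean_items) <= 0))
})

test_that("missing responses are skipped (or simulees dropped) as configured", {
  w <- midi_world()
  sub <- w$responses[1:6, ]
  sub[, w$bank$item_id[1:10]] <- NA    # knock out ten items for everyone
  sim <- run_simulated_cat(sub, w$bank, cat_config(se_stop = 8, seed = 2),
                           on_missing = "skip")
  admin <- unlist(lapply(sim$sessions, function(s) names(s$responses)))
  expect_false(any(admin %in% w$bank$item_id[1:10]))
  sim2 <- run_simulated_cat(sub, w$bank, cat_config(se_stop = 8, seed = 2),
                            on_missing = "drop")
  expect_identical(sim2$summary$n, 0L)
  expect_identical(sim2$dropped, 1:6)
})

test_that("tuning grid machinery selects dominant configurations", {
  expect_identical(nrow(default_tuning_grid()), 1200L)
  expect_identical(sort(names(default_tuning_grid())),
                   sort(c("se_stop", "remaining_info_stop", "top2_prob",
                          "max_items")))
  w <- midi_world()
  sub <- w$responses[1:20, ]
  expect_error(tune(sub, w$bank, data.frame()), "empty")
  single <- data.frame(se_stop = 6, remaining_info_stop = 0.1,
                       top2_prob = 0, max_items = 30)
  res1 <- tune(sub, w$bank, single)
  expect_identical(res1$best_row, 1L)
  expect_equal(res1$best$se_stop, 6)
  # a planted strictly dominant config (all items, exact scores) wins
  grid <- data.frame(se_stop = c(8, 1e-6),
                     remaining_info_stop = c(0.5, 0),
                     top2_prob = c(0, 0), max_items = c(5, 1000))
  res2 <- tune(sub, w$bank, grid, r_tol = 0.005)
  expect_identical(res2$best_row, 2L)  # r = 1 beats the short cheap config
})

test_that("score transform and severity categories respect their contracts", {
  tr <- score_transform()
  expect_equal(transform_score(tr, 0), 50)
  expect_equal(transform_score(tr, 10), 100)   # clipped
  expect_equal(transform_score(tr, -10), 0)
  th <- seq(-6, 6, 0.25)
  expect_true(all(transform_score(tr, th) >= 0 &
                    transform_score(tr, th) <= 100))
  expect_equal(transform_se(tr, 1/3), 5)
  expect_error(severity_thresholds(50, 40, 60), "ascending")
  expect_error(severity_thresholds(35, 47, 120), "0, 100")
  expect_identical(classify_severity(30), "none")
  expect_identical(classify_severity(47), "moderate")  # lower-inclusive
  expect_identical(classify_severity(c(0, 100)), c("none", "severe"))
  expect_error(classify_severity(101), "0, 100")
})
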