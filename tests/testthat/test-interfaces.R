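cli_tmp <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  d
}

test_that("synth subcommand is deterministic given a seed", {
  d1 <- cli_tmp(); d2 <- cli_tmp()
  args <- c("--n-items", "20", "--n-persons", "40", "--seed", "5")
  expect_identical(
    suppressMessages(catcad_cli(c("synth", args, "--out-dir", d1))), 0L)
  expect_identical(
    suppressMessages(catcad_cli(c("synth", args, "--out-dir", d2))), 0L)
  for (f in c("bank.tsv", "responses.tsv", "labels.tsv", "truth.tsv",
              "provenance.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("calibrate/filter pipeline runs end to end on synth output", {
  d <- cli_tmp()
  expect_identical(suppressMessages(catcad_cli(
    c("synth", "--n-items", "15", "--n-persons", "120", "--seed", "3",
      "--out-dir", d))), 0L)
  expect_identical(suppressWarnings(suppressMessages(catcad_cli(
    c("calibrate", "--bank", file.path(d, "bank.tsv"),
      "--responses", file.path(d, "responses.tsv"),
      "--quadrature-points", "7", "--max-iter", "40",
      "--out-dir", d)))), 0L)
  lrt <- jsonlite::read_json(file.path(d, "lr_test.json"))
  expect_gte(lrt$chi2, 0)
  expect_identical(lrt$df, 15L)
  expect_true(file.exists(file.path(d, "calibrated_bank.tsv")))
  expect_identical(suppressMessages(catcad_cli(
    c("filter", "--bank", file.path(d, "calibrated_bank.tsv"),
      "--min-loading", "0.3", "--out-dir", d))), 0L)
  fb <- read_bank(file.path(d, "filtered_bank.tsv"))
  expect_lte(nrow(fb), 15L)
  expect_true(all(standardized_loadings(fb$a0, fb$ag)$lambda0 >= 0.3))
})

test_that("cat-run writes a replayable session log", {
  d <- cli_tmp()
  fb_path <- system.file("extdata", "fixture_bank.tsv", package = "catcad")
  fb <- read_bank(fb_path)
  gr <- gen_responses(fb, n_persons = 3, seed = 778)
  rp <- file.path(d, "resp.tsv")
  write_responses(gr$responses, rp)
  expect_identical(suppressMessages(catcad_cli(
    c("cat-run", "--bank", fb_path, "--responses", rp,
      "--person", "p0002", "--seed", "4", "--out-dir", d))), 0L)
  log <- read_session_log(file.path(d, "session_p0002.log"))
  expect_identical(log$meta[["stop_reason"]], "precision")
  replayed <- replay_session(log, fb, cat_config(seed = 4))
  expect_equal(replayed$trajectory$score, log$trajectory$score,
               tolerance = 1e-9)
  expect_identical(replayed$trajectory$item_id, log$trajectory$item_id)
})

test_that("cad-train / cad-run / validate work from files", {
  d <- cli_tmp()
  w <- midi_world()
  rp <- file.path(d, "resp.tsv"); lp <- file.path(d, "lab.tsv")
  write_responses(w$responses, rp)
  utils::write.table(data.frame(person_id = rownames(w$responses),
                                label = w$labels),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(suppressMessages(catcad_cli(
    c("cad-train", "--responses", rp, "--labels", lp, "--n-forms", "2",
      "--seed", "6", "--out-dir", d))), 0L)
  expect_identical(suppressMessages(catcad_cli(
    c("cad-run", "--models", file.path(d, "cad_models.json"),
      "--responses", rp, "--person", "p0005", "--out-dir", d))), 0L)
  session <- jsonlite::read_json(file.path(d, "cad_session_p0005.json"))
  expect_lte(length(session$items), 6L)
  expect_gte(session$prob, 0); expect_lte(session$prob, 1)
  # validate from a scores file
  sc <- file.path(d, "scores.tsv")
  full <- eap_scores(w$responses, w$bank, quad_points = 21,
                     group_quad_points = 11)
  utils::write.table(
    data.frame(person_id = rownames(w$responses),
               score = transform_score(score_transform(), full$theta)),
    sc, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(suppressMessages(catcad_cli(
    c("validate", "--scores", sc, "--labels", lp, "--folds", "5",
      "--seed", "2", "--out-dir", d))), 0L)
  v <- jsonlite::read_json(file.path(d, "validation.json"))
  expect_gt(v$auc, 0.5)
})

test_that("the CLI contract rejects bad invocations nonzero", {
  expect_identical(suppressMessages(catcad_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(catcad_cli(character(0))), 2L)
  d <- cli_tmp()
  # missing required flag
  expect_identical(suppressMessages(catcad_cli(
    c("calibrate", "--out-dir", d))), 1L)
  # malformed input file
  bad <- file.path(d, "bad.tsv")
  writeLines("item_id\tnot_the_schema", bad)
  expect_identical(suppressMessages(catcad_cli(
    c("filter", "--bank", bad, "--out-dir", d))), 1L)
})

test_that("provenance blocks identify the producing configuration", {
  p1 <- provenance(list(a = 1), seed = 3)
  p2 <- provenance(list(a = 1), seed = 3)
  p3 <- provenance(list(a = 2), seed = 3)
  expect_identical(p1$config_hash, p2$config_hash)
  expect_false(identical(p1$config_hash, p3$config_hash))
  expect_identical(p1$version,
                   as.character(utils::packageVersion("catcad")))
})
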