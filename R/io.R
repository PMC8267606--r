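#' Write an item bank to a delimited text file
#'
#' Tab-separated schema: `item_id`, `subdomain`, `n_categories`, `a0`, `ag`,
#' `c_1 .. c_m` where `m` is the largest threshold count in the bank. Absent
#' parameters (uncalibrated items, or unused threshold columns) are empty.
#'
#' @param bank an [item_bank()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  m <- max(bank$n_categories) - 1L
  thr <- t(vapply(bank$thresholds, function(cv) {
    c(if (is.null(cv)) rep(NA_real_, m) else c(cv, rep(NA_real_, m - length(cv))))
  }, numeric(m)))
  df <- data.frame(item_id = bank$item_id, subdomain = bank$subdomain,
                   n_categories = bank$n_categories,
                   a0 = bank$a0, ag = bank$ag, stringsAsFactors = FALSE)
  colnames(thr) <- paste0("c_", seq_len(m))
  df <- cbind(df, thr)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an item bank from a delimited text file
#'
#' @param path file written by [write_bank()] (or following its schema).
#' @return an [item_bank()].
#' @export
read_bank <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("item_id", "subdomain", "n_categories")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("bank file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  ccols <- grep("^c_[0-9]+$", names(df), value = TRUE)
  ccols <- ccols[order(as.integer(sub("c_", "", ccols)))]
  thresholds <- lapply(seq_len(nrow(df)), function(j) {
    cv <- as.numeric(df[j, ccols])
    cv <- cv[!is.na(cv)]
    if (length(cv)) cv else NULL
  })
  item_bank(df$item_id, df$subdomain, df$n_categories,
            a0 = if ("a0" %in% names(df)) df$a0 else NULL,
            ag = if ("ag" %in% names(df)) df$ag else NULL,
            thresholds = thresholds,
            stem = if ("stem" %in% names(df)) df$stem else NULL)
}

#' Write a response matrix to a delimited text file
#'
#' Tab-separated, persons in rows with a leading `person_id` column, one
#' column per item; missing responses are empty cells.
#'
#' @param responses integer matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  if (is.null(rownames(responses))) {
    rownames(responses) <- sprintf("p%04d", seq_len(nrow(responses)))
  }
  df <- data.frame(person_id = rownames(responses), responses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a response matrix written by [write_responses()]
#'
#' @param path input path.
#' @param bank optional [item_bank()]; when given, codes are validated
#'   against it and offending cells are reported by row and column.
#' @return integer matrix, persons x items, `NA` = missing.
#' @export
read_responses <- function(path, bank = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE)
  if (!"person_id" %in% names(df)) stop("response file lacks person_id column")
  m <- as.matrix(df[, setdiff(names(df), "person_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$person_id
  if (!is.null(bank)) validate_responses(m, bank)
  m
}

#' Serialize CAD screener forms to structured text (JSON)
#'
#' Round-trip stable: [read_cad_models()] on the written file reproduces
#' [predict_proba()] outputs bit-exactly.
#'
#' @param models a `cad_model_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cad_models <- function(models, path) {
  payload <- list(
    format = "catcad-cad-models",
    version = as.character(utils::packageVersion("catcad")),
    forms = lapply(models, function(m) {
      list(seed = m$seed, degenerate = m$degenerate,
           prevalence = m$prevalence,
           item_max = as.list(m$item_max),
           weights = if (is.null(m$weights)) NULL else as.list(m$weights),
           config = unclass(m$config),
           trees = m$trees)
    }))
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

rebuild_tree <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", prob = as.numeric(node$prob),
         n = as.integer(node$n), pos = as.integer(node$pos))
  } else {
    list(type = "split", item = as.character(node$item),
         cut = as.numeric(node$cut),
         left = rebuild_tree(node$left), right = rebuild_tree(node$right))
  }
}

#' Read CAD screener forms written by [write_cad_models()]
#'
#' @param path input path.
#' @return a `cad_model_set`.
#' @export
read_cad_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "catcad-cad-models")) {
    stop("not a CAD model file: ", path)
  }
  forms <- lapply(payload$forms, function(f) {
    cfg <- f$config
    config <- cad_config(n_trees = cfg$n_trees, depth = cfg$depth,
                         n_forms = cfg$n_forms,
                         n_candidates = cfg$n_candidates,
                         min_node = cfg$min_node,
                         combination = cfg$combination,
                         threshold = cfg$threshold, seed = cfg$seed)
    m <- list(config = config, seed = f$seed,
              item_max = unlist(f$item_max),
              degenerate = isTRUE(f$degenerate),
              prevalence = as.numeric(f$prevalence),
              weights = if (is.null(f$weights)) NULL else unlist(f$weights),
              trees = lapply(f$trees, rebuild_tree))
    class(m) <- "cad_model"
    m
  })
  structure(forms, class = "cad_model_set")
}

#' Write a CAT session log
#'
#' Line-per-step tab-separated trajectory (step, item id, response, score,
#' uncertainty) preceded by `#`-prefixed provenance headers (stop reason,
#' seed, config hash, package version) so a session is replayable from its
#' log alone.
#'
#' @param session a finished `cat_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- provenance(unclass(session$config), session$config$seed)
  writeLines(c(
    paste0("# catcad session log v", prov$version),
    paste0("# seed=", session$config$seed),
    paste0("# config_hash=", prov$config_hash),
    paste0("# stop_reason=", session$stop_reason)), con)
  utils::write.table(
    format(session$trajectory, digits = 17, trim = TRUE, scientific = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CAT session log
#'
#' @param path log written by [write_session_log()].
#' @return list with `trajectory` (data frame) and `meta` (named character
#'   vector of the header fields).
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta_lines <- grep("=", hdr, value = TRUE)
  meta <- sub("^# *", "", meta_lines)
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  df$item_id <- as.character(df$item_id)
  list(trajectory = df, meta = meta)
}

#' Replay a logged session through the engine
#'
#' Re-runs the adaptive loop against the responses recorded in a session log;
#' with the same bank, configuration and seed the engine re-selects the same
#' items and reproduces the trajectory.
#'
#' @param log result of [read_session_log()] (or a trajectory data frame).
#' @param bank the calibrated [item_bank()] used originally.
#' @param config the original [cat_config()].
#' @param transform the original [score_transform()].
#' @return a finished `cat_session`.
#' @export
replay_session <- function(log, bank, config = cat_config(),
                           transform = score_transform()) {
  traj <- if (is.data.frame(log)) log else log$trajectory
  lookup <- stats::setNames(traj$response, traj$item_id)
  run_cat(bank, function(id) {
    if (id %in% names(lookup)) lookup[[id]] else NA_integer_
  }, config, transform, on_missing = "error")
}

# polynomial rolling hash over the bytes of a canonical deparse; cheap
# stable fingerprint for provenance blocks
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Provenance block for an artifact
#'
#' @param config list of settings that produced the artifact.
#' @param seed the seed used.
#' @return list with `version`, `seed`, `config_hash`.
#' @export
provenance <- function(config, seed) {
  list(version = as.character(utils::packageVersion("catcad")),
       seed = seed, config_hash = config_hash(config))
}
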