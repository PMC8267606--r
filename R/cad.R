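#' CAD training configuration
#'
#' The diagnostic screener is an ensemble of shallow extremely randomized
#' trees: 2 trees of depth 3 by default, so one administration can never need
#' more than 6 distinct items. Several alternative forms are trained from
#' distinct seeds so different patients can receive different (but similarly
#' performing) item sets.
#'
#' @param n_trees trees per form.
#' @param depth maximum tree depth (root = depth 0 splits allowed up to
#'   `depth` levels).
#' @param n_forms number of alternative forms trained from distinct seeds.
#' @param n_candidates candidate items drawn at each node; default
#'   `ceiling(sqrt(p))` where `p` is the number of items.
#' @param min_node minimum training observations in a node eligible for
#'   splitting, and minimum size of each child.
#' @param combination how the trees' leaf probabilities are combined:
#'   `"logistic"` fits a logistic regression of the label on the tree outputs
#'   (the default extra degree of freedom over a single tree), `"average"`
#'   takes their mean.
#' @param threshold decision threshold on the combined probability.
#' @param seed base seed; form `f` uses `seed + f`.
#' @return list of class `cad_config`.
#' @export
cad_config <- function(n_trees = 2, depth = 3, n_forms = 10,
                       n_candidates = NULL, min_node = 10,
                       combination = c("logistic", "average"),
                       threshold = 0.5, seed = 1L) {
  combination <- match.arg(combination)
  stopifnot(n_trees >= 1, depth >= 1, n_forms >= 1, min_node >= 1,
            threshold > 0, threshold < 1)
  structure(list(n_trees = as.integer(n_trees), depth = as.integer(depth),
                 n_forms = as.integer(n_forms), n_candidates = n_candidates,
                 min_node = as.integer(min_node), combination = combination,
                 threshold = threshold, seed = as.integer(seed)),
            class = "cad_config")
}

# grow one extremely randomized tree: at each node draw `k` candidate items
# uniformly, one uniform cutpoint each within the node's observed value
# range, keep the split with the largest Gini impurity decrease
grow_extra_tree <- function(X, y, depth, k, min_node) {
  build <- function(idx, d) {
    n <- length(idx)
    pos <- sum(y[idx])
    if (d >= depth || n < 2L * min_node || pos == 0L || pos == n) {
      return(list(type = "leaf", prob = pos / n, n = n, pos = pos))
    }
    Xn <- X[idx, , drop = FALSE]
    usable <- which(apply(Xn, 2L, function(v) max(v) > min(v)))
    if (length(usable) == 0L) {
      return(list(type = "leaf", prob = pos / n, n = n, pos = pos))
    }
    cand <- if (length(usable) <= k) usable else sample(usable, k)
    best <- NULL
    gini <- function(p, m) if (m == 0L) 0 else 2 * p * (1 - p) * m
    parent_imp <- gini(pos / n, n)
    for (j in cand) {
      v <- Xn[, j]
      cut <- stats::runif(1L, min(v), max(v))
      left <- v < cut
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      pl <- sum(y[idx][left]) / nl
      pr <- (pos - sum(y[idx][left])) / (n - nl)
      dec <- parent_imp - gini(pl, nl) - gini(pr, n - nl)
      if (is.null(best) || dec > best$dec) {
        best <- list(j = j, cut = cut, left = left, dec = dec)
      }
    }
    if (is.null(best) || best$dec <= 0) {
      return(list(type = "leaf", prob = pos / n, n = n, pos = pos))
    }
    list(type = "split", item = colnames(X)[best$j], cut = best$cut,
         left = build(idx[best$left], d + 1L),
         right = build(idx[!best$left], d + 1L))
  }
  build(seq_len(nrow(X)), 0L)
}

tree_predict_row <- function(tree, lookup) {
  node <- tree
  while (node$type == "split") {
    v <- lookup(node$item)
    node <- if (v < node$cut) node$left else node$right
  }
  node$prob
}

tree_items <- function(tree) {
  if (tree$type == "leaf") return(character(0))
  unique(c(tree$item, tree_items(tree$left), tree_items(tree$right)))
}

#' Train adaptive diagnostic screener forms
#'
#' Trains `n_forms` alternative extremely-randomized-trees ensembles against
#' a binary criterion diagnosis. Each form holds `n_trees` depth-limited trees
#' plus a linear combination of their leaf probabilities; administering a form
#' traverses the trees in order, so at most `n_trees * depth` distinct items
#' are presented.
#'
#' @param responses integer matrix, persons x items, ordinal codes treated as
#'   numeric; no missing values.
#' @param labels binary (0/1 or logical) criterion diagnosis per person.
#' @param config a [cad_config()].
#' @return list of class `cad_model_set` containing `cad_model` objects. A
#'   degenerate training set (constant labels) yields models flagged
#'   `degenerate` that return the prevalence for every input.
#' @export
train_cad <- function(responses, labels, config = cad_config()) {
  if (!is.matrix(responses) || is.null(colnames(responses))) {
    stop("responses must be a matrix with item ids as colnames")
  }
  if (anyNA(responses)) stop("CAD training requires complete responses")
  labels <- as.integer(labels)
  if (length(labels) != nrow(responses)) stop("labels must match rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  k <- config$n_candidates
  if (is.null(k)) k <- ceiling(sqrt(ncol(responses)))
  item_max <- apply(responses, 2L, max)
  degenerate <- length(unique(labels)) < 2L
  forms <- vector("list", config$n_forms)
  for (f in seq_len(config$n_forms)) {
    form_seed <- config$seed + f
    model <- list(config = config, seed = form_seed,
                  item_max = item_max, degenerate = degenerate,
                  prevalence = mean(labels))
    if (degenerate) {
      model$trees <- list()
      model$weights <- NULL
      warning("constant labels: degenerate CAD form returning the prevalence")
    } else {
      set.seed(form_seed)
      model$trees <- lapply(seq_len(config$n_trees), function(t) {
        grow_extra_tree(responses, labels, config$depth, k, config$min_node)
      })
      P <- vapply(model$trees, function(tr) {
        vapply(seq_len(nrow(responses)), function(i) {
          tree_predict_row(tr, function(id) responses[i, id])
        }, 0)
      }, numeric(nrow(responses)))
      if (config$combination == "logistic") {
        df <- as.data.frame(P)
        names(df) <- paste0("t", seq_len(ncol(P)))
        df$y <- labels
        fit <- tryCatch(
          suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial())),
          error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
          model$weights <- NULL   # fall back to simple averaging
        } else {
          model$weights <- stats::coef(fit)
        }
      } else {
        model$weights <- NULL
      }
    }
    class(model) <- "cad_model"
    forms[[f]] <- model
  }
  structure(forms, class = "cad_model_set")
}

combine_tree_probs <- function(model, p) {
  if (is.null(model$weights)) return(min(max(mean(p), 0), 1))
  eta <- model$weights[1L] + sum(model$weights[-1L] * p)
  as.numeric(stats::plogis(eta))
}

#' Predict the diagnosis probability from a complete response row
#'
#' @param model a `cad_model`.
#' @param row named numeric vector (or 1-row matrix) covering every item the
#'   model can request.
#' @return probability in `[0, 1]`.
#' @export
predict_proba <- function(model, row) {
  stopifnot(inherits(model, "cad_model"))
  if (is.matrix(row)) row <- row[1L, ]
  if (model$degenerate) return(model$prevalence)
  needed <- unique(unlist(lapply(model$trees, tree_items)))
  missing <- setdiff(needed, names(row))
  if (length(missing)) {
    stop("row is missing required item(s): ", paste(missing, collapse = ", "))
  }
  p <- vapply(model$trees, function(tr) {
    tree_predict_row(tr, function(id) row[[id]])
  }, 0)
  combine_tree_probs(model, p)
}

#' Administer a CAD form adaptively
#'
#' Traverses the form's trees in order. Each item is asked at most once per
#' session: when a later tree (or a later node of the same tree) needs an item
#' that was already answered, the earlier response is imputed, which can
#' shorten the session below `n_trees * depth` items.
#'
#' @param model a `cad_model`.
#' @param responder function of an item id returning the 0-based ordinal code.
#' @return list of class `cad_session`: `items` (presentation order, no
#'   repeats), `responses` (named), `prob`, `screen` (logical, `prob >=`
#'   decision threshold).
#' @export
administer <- function(model, responder) {
  stopifnot(inherits(model, "cad_model"))
  answers <- new.env(parent = emptyenv())
  order_asked <- character(0)
  lookup <- function(id) {
    if (exists(id, envir = answers, inherits = FALSE)) {
      return(get(id, envir = answers))
    }
    v <- responder(id)
    kmax <- model$item_max[[id]]
    if (is.na(v) || !is.numeric(v) || v < 0 || v > kmax || v != floor(v)) {
      stop("invalid response for item '", id, "': expected an integer in 0..",
           kmax)
    }
    assign(id, v, envir = answers)
    order_asked <<- c(order_asked, id)
    v
  }
  prob <- if (model$degenerate) model$prevalence else {
    p <- vapply(model$trees, function(tr) tree_predict_row(tr, lookup), 0)
    combine_tree_probs(model, p)
  }
  structure(list(items = order_asked,
                 responses = stats::setNames(
                   vapply(order_asked, function(id) get(id, envir = answers),
                          0),
                   order_asked),
                 prob = prob,
                 screen = prob >= model$config$threshold),
            class = "cad_session")
}

#' Randomly select one screener form for a patient
#'
#' @param models a `cad_model_set` (or list of `cad_model`).
#' @param seed integer seed for the uniform draw.
#' @return one `cad_model`.
#' @export
select_form <- function(models, seed = 1L) {
  if (length(models) == 0L) stop("no CAD forms to select from")
  if (length(models) == 1L) return(models[[1L]])
  set.seed(seed)
  models[[sample.int(length(models), 1L)]]
}

#' @export
print.cad_model <- function(x, ...) {
  if (x$degenerate) {
    cat("CAD form (degenerate): constant probability ", x$prevalence, "\n",
        sep = "")
  } else {
    items <- unique(unlist(lapply(x$trees, tree_items)))
    cat("CAD form: ", length(x$trees), " tree(s), depth <= ",
        x$config$depth, ", ", length(items), " reachable item(s), ",
        if (is.null(x$weights)) "averaged" else "logistic", " combination\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.cad_model_set <- function(x, ...) {
  cat("CAD model set: ", length(x), " alternative form(s)\n", sep = "")
  invisible(x)
}
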