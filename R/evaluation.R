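#' ROC curve points
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary labels (0/1 or logical).
#' @return data frame of `(fpr, tpr)` points, monotone nondecreasing in both
#'   coordinates, from (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  check_binary(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # step only after the last tied score
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(1 - y) / sum(1 - y)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Area under the ROC curve (rank method)
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that a
#' random positive outscores a random negative, counting ties as 1/2.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  check_binary(labels)
  n1 <- sum(labels); n0 <- sum(1 - labels)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_binary <- function(labels) {
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("both classes must be present")
  }
  invisible(labels)
}

# DeLong variance of the AUC estimate
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  x <- scores[labels == 1L]   # positives
  y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), 0)
  v01 <- vapply(y, function(b) mean(psi(x, b)), 0)
  a <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, a - z * se), upper = min(1, a + z * se))
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign_fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign_fold
}

#' Cross-validated AUC of a score against a binary criterion
#'
#' Splits the data into label-stratified folds, fits (by default) a logistic
#' regression of the label on the score within each training fold, pools the
#' out-of-fold predictions, and computes the ROC/AUC on the pooled
#' predictions, with a DeLong 95% CI.
#'
#' @inheritParams roc_points
#' @param folds number of folds (>= 2); `folds = length(labels)` gives
#'   leave-one-out.
#' @param seed seed for the fold assignment.
#' @param use_logistic fit a per-fold logistic calibration (the severity-score
#'   pathway); `FALSE` passes scores through unchanged (already probabilities).
#' @return list of class `roc_result`: `auc`, `ci`, `roc` (points),
#'   `predictions` (pooled out-of-fold), `fold` assignments.
#' @export
cv_auc <- function(scores, labels, folds = 10, seed = 1L,
                   use_logistic = TRUE) {
  labels <- as.integer(labels)
  check_binary(labels)
  if (folds < 2L || folds > length(labels)) stop("folds must be in 2..n")
  fold <- stratified_folds(labels, folds, seed)
  pred <- numeric(length(labels))
  for (f in seq_len(folds)) {
    test <- fold == f
    if (use_logistic) {
      df <- data.frame(y = labels[!test], x = scores[!test])
      fit <- suppressWarnings(
        stats::glm(y ~ x, data = df, family = stats::binomial()))
      pred[test] <- stats::predict(fit, data.frame(x = scores[test]),
                                   type = "response")
    } else {
      pred[test] <- scores[test]
    }
  }
  structure(list(auc = auc(pred, labels),
                 ci = delong_ci(pred, labels),
                 roc = roc_points(pred, labels),
                 predictions = pred, fold = fold),
            class = "roc_result")
}

#' Cross-validated AUC of the CAD screener
#'
#' Retrains one screener form per training fold and scores the held-out fold
#' with [predict_proba()]; pooled out-of-fold probabilities give the AUC.
#'
#' @param responses complete integer response matrix.
#' @param labels binary diagnosis.
#' @param config a [cad_config()]; one form (`n_forms = 1`) per fold.
#' @param folds,seed as in [cv_auc()].
#' @return a `roc_result`.
#' @export
cv_auc_cad <- function(responses, labels, config = cad_config(),
                       folds = 10, seed = 1L) {
  labels <- as.integer(labels)
  check_binary(labels)
  fold <- stratified_folds(labels, folds, seed)
  pred <- numeric(length(labels))
  cfg <- config
  cfg$n_forms <- 1L
  for (f in seq_len(folds)) {
    test <- fold == f
    cfg$seed <- config$seed + f
    models <- train_cad(responses[!test, , drop = FALSE], labels[!test], cfg)
    for (i in which(test)) {
      pred[i] <- predict_proba(models[[1L]], responses[i, ])
    }
  }
  structure(list(auc = auc(pred, labels),
                 ci = delong_ci(pred, labels),
                 roc = roc_points(pred, labels),
                 predictions = pred, fold = fold),
            class = "roc_result")
}

#' Sensitivity and specificity at a threshold
#'
#' Positive call is `score >= threshold`. With no positive (or no negative)
#' cases the corresponding rate is `NA` -- an explicit undefined marker, not
#' zero.
#'
#' @inheritParams roc_points
#' @param threshold decision cut.
#' @return list with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  pos <- labels == 1L
  call_pos <- scores >= threshold
  list(
    sensitivity = if (any(pos)) mean(call_pos[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!call_pos[!pos]) else NA_real_
  )
}

#' Severity threshold selection policy
#'
#' Operationalizes "high sensitivity / moderate specificity" (none vs mild),
#' "high sensitivity and high specificity" (mild vs moderate) and "high
#' specificity" (moderate vs severe) as constrained searches over candidate
#' cuts: `t1` is the largest cut keeping sensitivity at or above
#' `sens_target`, `t2` maximizes Youden's J, and `t3` is the smallest cut
#' reaching specificity `spec_target`.
#'
#' @param sens_target sensitivity floor for the none/mild cut.
#' @param spec_target specificity floor for the moderate/severe cut.
#' @return list of class `threshold_policy`.
#' @export
threshold_policy <- function(sens_target = 0.95, spec_target = 0.93) {
  stopifnot(sens_target >= 0, sens_target <= 1,
            spec_target >= 0, spec_target <= 1)
  structure(list(sens_target = sens_target, spec_target = spec_target),
            class = "threshold_policy")
}

#' Select severity category thresholds against a binary criterion
#'
#' @param scores severity scores on the reporting scale.
#' @param labels binary criterion diagnosis.
#' @param policy a [threshold_policy()].
#' @return on success, a list with `thresholds` (a [severity_thresholds()])
#'   and the achieved `sens_spec` at each cut, plus `success = TRUE`; if the
#'   constraints cannot produce a strictly ascending triple, `success = FALSE`
#'   with the achievable `frontier` (candidate cut, sensitivity, specificity).
#' @export
select_thresholds <- function(scores, labels, policy = threshold_policy()) {
  labels <- as.integer(labels)
  check_binary(labels)
  cuts <- sort(unique(scores))
  frontier <- data.frame(
    cut = cuts,
    sensitivity = vapply(cuts, function(t) sens_spec(scores, labels, t)$sensitivity, 0),
    specificity = vapply(cuts, function(t) sens_spec(scores, labels, t)$specificity, 0))
  ok1 <- frontier$sensitivity >= policy$sens_target
  ok3 <- frontier$specificity >= policy$spec_target
  fail <- function() list(success = FALSE, frontier = frontier)
  if (!any(ok1) || !any(ok3)) return(fail())
  t1 <- max(frontier$cut[ok1])
  t3 <- min(frontier$cut[ok3])
  youden <- frontier$sensitivity + frontier$specificity - 1
  t2 <- frontier$cut[which.max(youden)]
  if (!(t1 < t2 && t2 < t3)) return(fail())
  thr <- severity_thresholds(t1, t2, t3)
  list(success = TRUE, thresholds = thr,
       achieved = frontier[frontier$cut %in% c(t1, t2, t3), ],
       frontier = frontier)
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and two-sided `p` from the t-test.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d folds\n",
              x$auc, x$ci[["lower"]], x$ci[["upper"]],
              length(unique(x$fold))))
  invisible(x)
}
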