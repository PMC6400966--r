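#' Confusion counts at a probability threshold
#'
#' Tabulates TP/FP/TN/FN for binary predictions, with phages as the positive
#' class by convention.
#'
#' @param scores Numeric vector of positive-class probabilities or scores.
#' @param labels Vector (factor, character or 0/1) of true classes.
#' @param positive Label of the positive class.
#' @param threshold Binarization threshold; predictions with
#'   `score >= threshold` are called positive. The default 0.5 is the
#'   threshold used throughout for MCC and accuracy.
#' @return Named list with integer elements `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, positive = CLASS_PHAGE,
                             threshold = 0.5) {
  truth <- as_binary_labels(labels, positive)
  pred <- as.integer(scores >= threshold)
  list(
    tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L)
  )
}

as_binary_labels <- function(labels, positive) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

#' Matthews correlation coefficient
#'
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) /
#' \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, a confusion-matrix correlation in
#' `[-1, 1]` that is robust to class imbalance. When any factor of the
#' denominator is zero the coefficient is defined as 0.
#'
#' @param counts Named list with elements `tp`, `fp`, `tn`, `fn` (as from
#'   [confusion_counts()]).
#' @return A number in `[-1, 1]`.
#' @examples
#' mcc(list(tp = 3, fp = 1, tn = 4, fn = 2)) # 10 / sqrt(600)
#' @export
mcc <- function(counts) {
  n <- unlist(counts[c("tp", "fp", "tn", "fn")])
  if (anyNA(n) || any(n < 0)) stopf("counts must be non-negative tp/fp/tn/fn")
  tp <- n[["tp"]]; fp <- n[["fp"]]; tn <- n[["tn"]]; fn <- n[["fn"]]
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Receiver operating characteristic curve
#'
#' Sweeps the decision threshold over all distinct scores (plus sentinels at
#' the extremes) and records the false- and true-positive rates. The curve
#' starts at (0, 0) and ends at (1, 1); tied scores produce diagonal
#' segments so that the trapezoidal area equals the rank-based (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @inheritParams confusion_counts
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the strictest threshold to the most permissive.
#' @export
roc_curve <- function(scores, labels, positive = CLASS_PHAGE) {
  truth <- as_binary_labels(labels, positive)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each distinct-score cut
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(t)[last_of_tie]
  fp <- cumsum(1L - t)[last_of_tie]
  data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; threshold-independent ranking
#' quality in `[0, 1]`, equal to the probability that a random positive
#' scores above a random negative (ties counted one half).
#'
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auc <- function(scores, labels, positive = CLASS_PHAGE) {
  rc <- roc_curve(scores, labels, positive)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Cross-validated model-selection fitness
#'
#' The scalar criterion used to select classifiers:
#' \deqn{fitness = \bar{MCC} + \bar{AUC} - \sigma_{MCC}/4 - \sigma_{AUC}/4}
#' i.e. mean cross-validation MCC and AUC rewarded, their fold-to-fold
#' dispersion penalized at a quarter weight. Its global maximum is 2
#' (perfect, zero-variance classification). Standard deviations are
#' population SDs over the fold values.
#'
#' @param x Either a cross-validation result from [cross_validate()], or the
#'   mean MCC (then supply the remaining three summaries).
#' @param mean_auc,sd_mcc,sd_auc Fold summaries when `x` is the mean MCC.
#' @return A single number, at most 2.
#' @examples
#' fitness(0.9, mean_auc = 0.95, sd_mcc = 0.04, sd_auc = 0.02) # 1.835
#' @export
fitness <- function(x, mean_auc = NULL, sd_mcc = NULL, sd_auc = NULL) {
  if (inherits(x, "vh_cv_result")) {
    s <- x$summary
    return(s$mean_mcc + s$mean_auc - s$sd_mcc / 4 - s$sd_auc / 4)
  }
  if (is.null(mean_auc) || is.null(sd_mcc) || is.null(sd_auc)) {
    stopf("supply a cross-validation result or all four fold summaries")
  }
  x + mean_auc - sd_mcc / 4 - sd_auc / 4
}

#' Construct stratified cross-validation folds
#'
#' Random fold assignment preserving class proportions in every fold.
#'
#' @param y Class labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold indices in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = 1L) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

#' Cross-validate a classifier configuration
#'
#' Runs k-fold cross-validation of one algorithm/hyperparameter
#' configuration: for each fold a model is trained on the remaining folds
#' only (standardization refitted on the training folds each time,
#' [train_classifier()]), held-out samples are scored, and per-fold MCC (at
#' threshold 0.5), AUC and accuracy are recorded. Fold means, population
#' standard deviations and the [fitness()] scalar summarize the result.
#'
#' @param X Raw (unstandardized) feature matrix.
#' @param y Class labels; phages are the positive class.
#' @param algorithm One of `"lr"`, `"knn"`, `"qda"`, `"svc"`.
#' @param folds Either a fold count (stratified random folds are built with
#'   `seed`) or an integer vector assigning each row of `X` to a fold.
#' @param seed Integer seed (fold construction and any training randomness).
#' @param positive Positive class label.
#' @param ... Hyperparameters passed on to [train_classifier()] (`C`, `k`).
#' @return Object of class `vh_cv_result`: list with `folds` (per-fold data
#'   frame), `summary` (means and SDs), `fitness`, `scores` (out-of-fold
#'   positive-class probability for every sample), `fold_assignment`.
#' @export
cross_validate <- function(X, y, algorithm = c("lr", "knn", "qda", "svc"),
                           folds = 5L, seed = 1L, positive = CLASS_PHAGE, ...) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(folds) == 1L) {
    folds <- stratified_folds(y, n_folds = as.integer(folds), seed = seed)
  }
  if (length(folds) != nrow(X)) {
    stopf("fold assignment length (%d) != number of samples (%d)",
          length(folds), nrow(X))
  }
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2L) stopf("need at least 2 folds")
  scores <- rep(NA_real_, nrow(X))
  per_fold <- lapply(fold_ids, function(f) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (length(unique(y[test_idx])) < 2L) {
      stopf("fold %s does not contain both classes", f)
    }
    m <- train_classifier(X[train_idx, , drop = FALSE], y[train_idx],
      algorithm = algorithm, seed = seed, positive = positive, ...
    )
    p <- predict_proba(m, X[test_idx, , drop = FALSE])[, positive]
    scores[test_idx] <<- p
    cc <- confusion_counts(p, y[test_idx], positive = positive)
    data.frame(
      fold = f,
      mcc = mcc(cc),
      auc = auc(p, y[test_idx], positive = positive),
      accuracy = (cc$tp + cc$tn) / length(test_idx)
    )
  })
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(
    mean_mcc = mean(per_fold$mcc),
    mean_auc = mean(per_fold$auc),
    mean_accuracy = mean(per_fold$accuracy),
    sd_mcc = sd_pop(per_fold$mcc),
    sd_auc = sd_pop(per_fold$auc)
  )
  out <- structure(
    list(
      folds = per_fold, summary = summary,
      scores = scores, fold_assignment = folds,
      algorithm = algorithm, seed = seed
    ),
    class = "vh_cv_result"
  )
  out$fitness <- fitness(out)
  out
}

#' @export
print.vh_cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d-fold cross-validation (%s)\n  MCC  %.3f +/- %.3f\n  AUC  %.3f +/- %.3f\n  accuracy %.3f\n  fitness  %.4f\n",
    nrow(x$folds), x$algorithm,
    s$mean_mcc, s$sd_mcc, s$mean_auc, s$sd_auc, s$mean_accuracy, x$fitness
  ))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param cv A `vh_cv_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(cv, path) {
  jsonlite::write_json(
    list(
      algorithm = cv$algorithm,
      folds = cv$folds,
      summary = cv$summary,
      fitness = cv$fitness
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write ROC curve points as TSV
#'
#' @param rc Data frame from [roc_curve()].
#' @param path Output path (columns fpr, tpr, threshold).
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(rc, path) {
  utils::write.table(rc[, c("fpr", "tpr", "threshold")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
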