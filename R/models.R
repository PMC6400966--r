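#' Train a host-taxon classifier
#'
#' Fits one of the four supported binary classifiers on a feature matrix:
#' L2-regularized logistic regression (`"lr"`, via glmnet), k-nearest
#' neighbours (`"knn"`), quadratic discriminant analysis (`"qda"`) or a
#' linear-kernel support vector classifier (`"svc"`, via e1071 with Platt
#' scaling fitted on the training decision values). Standardization
#' parameters are fitted on the training matrix only and stored inside the
#' model, so a trained model is self-contained: raw feature vectors can be
#' passed to [predict_proba()] directly.
#'
#' @param X Raw feature matrix (rows = samples, columns named after
#'   [feature_schema()] or any consistent feature set).
#' @param y Class labels with exactly two classes; phages are the positive
#'   class by convention.
#' @param algorithm `"lr"`, `"knn"`, `"qda"` or `"svc"`.
#' @param C Regularization strength for `lr`/`svc` (inverse penalty, the
#'   conventional grid is the powers of two from 2^-5 to 2^5; default 1).
#' @param k Neighbour count for `knn`; odd, conventionally in 1, 3, 5, 7, 9.
#' @param feature_subset Optional subset of features to train on: column
#'   names, integer indices, or a logical mask over the columns of `X`.
#' @param seed Integer seed for any training randomness.
#' @param positive Positive class label (default `"phage"`).
#' @return Object of class `vh_model` storing the fitted parameters, the
#'   standardization parameters, the feature subset and the class labels.
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' y <- rep(c("phage", "eukaryote-infecting"), each = 10)
#' m <- train_classifier(X, y, "lr")
#' predict_proba(m, X[1:2, ])
#' @export
train_classifier <- function(X, y, algorithm = c("lr", "knn", "qda", "svc"),
                             C = 1, k = 5L, feature_subset = NULL,
                             seed = 1L, positive = CLASS_PHAGE) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stopf("feature matrix contains non-finite values")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stopf("y must contain exactly 2 classes, got %d", length(classes))
  }
  if (min(table(y)) < 2L) stopf("need at least 2 samples per class")
  if (!positive %in% classes) positive <- classes[2L]
  negative <- setdiff(classes, positive)
  if (!is.null(C) && C <= 0) stopf("C must be positive")
  k <- as.integer(k)
  if (algorithm == "knn" && (k < 1L || k %% 2L == 0L)) {
    stopf("k must be a positive odd integer")
  }

  X <- restrict_columns(X, feature_subset)
  std <- fit_standardization(X)
  Z <- standardize(X, std)
  y01 <- as.integer(y == positive)

  fit <- switch(algorithm,
    lr = fit_lr(Z, y01, C),
    knn = list(Z = Z, y01 = y01, k = k),
    qda = fit_qda(Z, y01),
    svc = fit_svc(Z, y01, C, seed)
  )

  structure(
    list(
      algorithm = algorithm,
      hyperparameters = list(C = C, k = k),
      feature_names = colnames(Z),
      standardization = std,
      classes = c(negative = negative, positive = positive),
      fit = fit,
      seed = seed,
      format_version = 1L
    ),
    class = "vh_model"
  )
}

restrict_columns <- function(X, feature_subset) {
  if (is.null(feature_subset)) return(X)
  if (is.logical(feature_subset)) feature_subset <- which(feature_subset)
  if (is.character(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(X))
    if (length(missing) > 0L) {
      stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
    }
  }
  X <- X[, feature_subset, drop = FALSE]
  if (ncol(X) < 1L) stopf("feature subset must keep at least one feature")
  X
}

fit_lr <- function(Z, y01, C) {
  n <- nrow(Z)
  lambda <- 1 / (n * C)
  # glmnet needs >= 2 columns; pad 1-D problems with a zero column
  pad <- ncol(Z) == 1L
  Zf <- if (pad) cbind(Z, `..pad` = 0) else Z
  path <- exp(seq(log(lambda * 1000), log(lambda), length.out = 20L))
  path[20L] <- lambda
  g <- glmnet::glmnet(Zf, y01,
    family = "binomial", alpha = 0, lambda = path,
    standardize = FALSE
  )
  cf <- if (length(g$lambda) > 1L) {
    as.numeric(coef(g, s = lambda, exact = FALSE))
  } else {
    as.numeric(coef(g))
  }
  list(intercept = cf[1L], coefficients = cf[-1L][seq_len(ncol(Z))])
}

fit_qda <- function(Z, y01) {
  # Gaussian class-conditional model with a ridge fallback so singular
  # class covariances (degenerate or low-complexity inputs) never crash.
  per_class <- lapply(c(0L, 1L), function(cl) {
    Zi <- Z[y01 == cl, , drop = FALSE]
    mu <- colMeans(Zi)
    S <- stats::cov(Zi)
    ridge <- 0
    repeat {
      R <- tryCatch(chol(S + diag(ridge, ncol(Z))), error = function(e) NULL)
      if (!is.null(R)) break
      ridge <- if (ridge == 0) 1e-9 else ridge * 10
      if (ridge > 1) stopf("QDA covariance irreparably singular")
    }
    list(
      mean = mu, chol = R,
      logdet = 2 * sum(log(diag(R))),
      prior = mean(y01 == cl)
    )
  })
  names(per_class) <- c("neg", "pos")
  per_class
}

fit_svc <- function(Z, y01, C, seed) {
  yf <- factor(y01, levels = c(0L, 1L))
  svm_fit <- with_seed(seed, e1071::svm(Z, yf,
    kernel = "linear", cost = C, scale = FALSE, probability = FALSE,
    type = "C-classification"
  ))
  dv <- decision_values(svm_fit, Z)
  # Platt-style sigmoid calibration on the training decision values
  platt <- suppressWarnings(glm(y01 ~ dv, family = binomial()))
  list(svm = svm_fit, platt = coef(platt))
}

decision_values <- function(svm_fit, Z) {
  dv <- attr(predict(svm_fit, Z, decision.values = TRUE), "decision.values")
  dv <- as.numeric(dv[, 1L])
  # e1071 orients decision values by the first class seen; with levels
  # fixed to c(0, 1) the column name tells us the sign convention
  dv
}

#' Predict class probabilities
#'
#' Scores new feature vectors with a trained model. Input is standardized
#' with the model's stored parameters and restricted to the model's feature
#' subset (a wider matrix carrying named columns is restricted
#' automatically; an unnamed matrix must already match the subset).
#'
#' @param model A `vh_model` from [train_classifier()].
#' @param newX Feature matrix or single feature vector (raw scale).
#' @return Numeric matrix with one row per input and one column per class
#'   (negative class first, positive class second); rows sum to 1.
#' @export
predict_proba <- function(model, newX) {
  if (!inherits(model, "vh_model")) stopf("model must be a vh_model")
  if (is.null(dim(newX))) {
    newX <- matrix(newX, nrow = 1L, dimnames = list(NULL, names(newX)))
  }
  newX <- as.matrix(newX)
  fn <- model$feature_names
  if (!is.null(colnames(newX))) {
    if (!all(fn %in% colnames(newX))) {
      stopf("input lacks model feature(s): %s",
            paste(setdiff(fn, colnames(newX)), collapse = ", "))
    }
    newX <- newX[, fn, drop = FALSE]
  } else if (ncol(newX) != length(fn)) {
    stopf("input has %d features but the model uses %d", ncol(newX), length(fn))
  } else {
    colnames(newX) <- fn
  }
  Z <- standardize(newX, model$standardization)
  p_pos <- switch(model$algorithm,
    lr = {
      eta <- model$fit$intercept + as.numeric(Z %*% model$fit$coefficients)
      1 / (1 + exp(-eta))
    },
    knn = knn_proba(model$fit, Z),
    qda = qda_proba(model$fit, Z),
    svc = {
      dv <- decision_values(model$fit$svm, Z)
      eta <- model$fit$platt[1L] + model$fit$platt[2L] * dv
      1 / (1 + exp(-eta))
    }
  )
  out <- cbind(1 - p_pos, p_pos)
  colnames(out) <- unname(model$classes[c("negative", "positive")])
  rownames(out) <- rownames(newX)
  out
}

knn_proba <- function(fit, Z) {
  vapply(seq_len(nrow(Z)), function(i) {
    d <- sqrt(colSums((t(fit$Z) - Z[i, ])^2))
    # ties in distance broken by lowest training index (stable, seeded-free)
    nbrs <- order(d, seq_along(d))[seq_len(min(fit$k, length(d)))]
    mean(fit$y01[nbrs])
  }, numeric(1))
}

qda_proba <- function(fit, Z) {
  loglik <- vapply(fit, function(cl) {
    centered <- sweep(Z, 2L, cl$mean, "-")
    # Mahalanobis terms via the stored Cholesky factor
    w <- backsolve(cl$chol, t(centered), transpose = TRUE)
    -0.5 * (cl$logdet + colSums(w^2)) + log(cl$prior)
  }, numeric(nrow(Z)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1L)
  m <- pmax(loglik[, 1L], loglik[, 2L])
  num <- exp(loglik[, 2L] - m)
  num / (num + exp(loglik[, 1L] - m))
}

#' Predict hard labels or probabilities
#'
#' @param object A `vh_model`.
#' @param newX Feature matrix or vector (raw scale).
#' @param type `"class"` for hard labels at threshold 0.5, `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return Character vector of labels, or the matrix from [predict_proba()].
#' @export
predict.vh_model <- function(object, newX, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newX)
  if (type == "prob") return(p)
  pos <- unname(object$classes["positive"])
  neg <- unname(object$classes["negative"])
  ifelse(p[, pos] >= 0.5, pos, neg)
}

#' @export
print.vh_model <- function(x, ...) {
  cat(sprintf(
    "viralhost classifier (%s): %d features, classes %s (positive: %s)\n",
    x$algorithm, length(x$feature_names),
    paste(x$classes, collapse = " / "), x$classes[["positive"]]
  ))
  invisible(x)
}

#' Save a trained model to a single file
#'
#' Serializes the model together with a format version so that stale or
#' foreign files are rejected on load. The round trip is exact: a reloaded
#' model reproduces probabilities bit-identically.
#'
#' @param model A `vh_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "vh_model")) stopf("model must be a vh_model")
  saveRDS(list(format = "viralhost_model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a trained model saved with [save_model()]
#'
#' @param path Path to a saved model file.
#' @return The `vh_model`.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stopf("cannot read model file %s: %s", path, conditionMessage(e))
  })
  if (!is.list(bundle) || !identical(bundle$format, "viralhost_model")) {
    stopf("%s is not a viralhost model file", path)
  }
  if (!identical(bundle$version, 1L)) {
    stopf("unsupported model format version: %s", bundle$version)
  }
  bundle$model
}
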