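make_toy <- function(n = 20, seed = 15) {
  withr::with_seed(seed, {
    X <- cbind(x1 = c(rnorm(n / 2, -1, 0.3), rnorm(n / 2, 1, 0.3)),
               x2 = rnorm(n))
    y <- rep(c("eukaryote-infecting", "phage"), each = n / 2)
    list(X = X, y = y)
  })
}

test_that("1-nearest-neighbour is certain about its own training points", {
  X <- cbind(a = c(0, 0.1, 5, 5.1), b = c(0, 0.1, 5, 5.1))
  y <- c("phage", "phage", "eukaryote-infecting", "eukaryote-infecting")
  m <- train_classifier(X, y, "knn", k = 1)
  p <- predict_proba(m, X)
  expect_equal(unname(p[, "phage"]), c(1, 1, 0, 0))
  expect_identical(unname(predict(m, X)),
                   c("phage", "phage", "eukaryote-infecting", "eukaryote-infecting"))
})

test_that("logistic regression ranks perfectly separable toy data perfectly", {
  toy <- make_toy()
  m <- train_classifier(toy$X[, 1, drop = FALSE], toy$y, "lr")
  p <- predict_proba(m, toy$X[, 1, drop = FALSE])[, "phage"]
  expect_equal(auc(p, toy$y), 1)
})

test_that("QDA agrees with the reference discriminant implementation", {
  skip_if_not_installed("MASS")
  toy <- make_toy(n = 60, seed = 31)
  m <- train_classifier(toy$X, toy$y, "qda")
  p <- predict_proba(m, toy$X)[, "phage"]
  # same standardized inputs to the reference fit
  Z <- standardize(toy$X, m$standardization)
  ref <- MASS::qda(Z, grouping = factor(toy$y))
  p_ref <- predict(ref, Z)$posterior[, "phage"]
  expect_equal(unname(p), unname(p_ref), tolerance = 1e-6)
})

test_that("QDA decision boundary sits between equal-variance classes", {
  withr::with_seed(99, {
    n <- 1000
    X <- cbind(x = c(rnorm(n, -1), rnorm(n, 1)))
    y <- rep(c("eukaryote-infecting", "phage"), each = n)
  })
  m <- train_classifier(X, y, "qda")
  # with symmetric classes the posterior at the midpoint is ~0.5
  p_mid <- predict_proba(m, cbind(x = 0))[, "phage"]
  expect_lt(abs(p_mid - 0.5), 0.05)
})

test_that("QDA survives singular class covariances via the ridge fallback", {
  X <- cbind(a = c(1, 1, 1, 2, 3, 4), b = c(2, 2, 2, 5, 6, 7))
  y <- c(rep("phage", 3), rep("eukaryote-infecting", 3))
  # class "phage" has zero covariance; must not crash
  m <- train_classifier(X, y, "qda")
  p <- predict_proba(m, X)
  expect_true(all(is.finite(p)))
})

test_that("probabilities are proper for every algorithm", {
  sep <- separated_corpus()
  X <- sep$X
  y <- sep$corpus$class
  for (alg in c("lr", "knn", "qda", "svc")) {
    m <- train_classifier(X, y, alg, seed = 5)
    p <- predict_proba(m, X[1:10, ])
    expect_true(all(p >= 0 & p <= 1), info = alg)
    expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-9)
    lab <- predict(m, X[1:10, ])
    expect_identical(unname(lab),
                     unname(ifelse(p[, "phage"] >= 0.5, "phage", "eukaryote-infecting")))
  }
})

test_that("every algorithm separates the synthetic corpus on held-out data", {
  sep <- separated_corpus()
  part <- partition_viruses(sep$corpus, seed = 12)
  is_cv <- grepl("^cv", part$split)
  is_test <- part$split == "test"
  cv_ids <- part$id[is_cv]
  test_ids <- part$id[is_test]
  y <- setNames(sep$corpus$class, sep$corpus$id)
  for (alg in c("lr", "knn", "qda", "svc")) {
    m <- train_classifier(sep$X[cv_ids, ], y[cv_ids], alg, seed = 5)
    p <- predict_proba(m, sep$X[test_ids, ])[, "phage"]
    expect_gt(auc(p, y[test_ids]), 0.9)
  }
})

test_that("chance-level data stays at chance end to end (null control)", {
  nul <- null_corpus()
  cv <- cross_validate(nul$X, nul$corpus$class, "lr", folds = 5, seed = 6)
  expect_lt(abs(cv$summary$mean_auc - 0.5), 0.1)
})

test_that("training is invariant to sample order for lr, qda and svc", {
  sep <- separated_corpus()
  X <- sep$X
  y <- sep$corpus$class
  perm <- withr::with_seed(44, sample(nrow(X)))
  for (alg in c("lr", "qda", "svc")) {
    m1 <- train_classifier(X, y, alg, seed = 5)
    m2 <- train_classifier(X[perm, ], y[perm], alg, seed = 5)
    p1 <- predict_proba(m1, X[1:8, ])
    p2 <- predict_proba(m2, X[1:8, ])
    expect_equal(p1, p2, tolerance = 1e-6, info = alg)
  }
})

test_that("models round-trip through disk bit-identically", {
  sep <- separated_corpus()
  for (alg in c("lr", "knn", "qda", "svc")) {
    m <- train_classifier(sep$X, sep$corpus$class, alg,
                          feature_subset = 1:20, seed = 5)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(predict_proba(m, sep$X[1:5, ]),
                     predict_proba(m2, sep$X[1:5, ]))
  }
})

test_that("model files reject corruption and schema mismatch", {
  sep <- separated_corpus()
  m <- train_classifier(sep$X, sep$corpus$class, "lr", feature_subset = 1:10)
  garbage <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", garbage)
  expect_error(load_model(garbage), "model file")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), other)
  expect_error(load_model(other), "not a viralhost model")
  # wrong input width
  expect_error(predict_proba(m, matrix(0, 1, 3)), "features")
})

test_that("invalid training inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_classifier(X, rep("phage", 10), "lr"), "2 classes")
  Xna <- X; Xna[1, 1] <- NaN
  expect_error(train_classifier(Xna, rep(c("phage", "x"), 5), "lr"), "non-finite")
  expect_error(train_classifier(X, rep(c("phage", "x"), 5), "knn", k = 4), "odd")
  expect_error(train_classifier(X, rep(c("phage", "x"), 5), "lr", C = -1), "positive")
  expect_error(
    train_classifier(X, rep(c("phage", "x"), 5), "lr", feature_subset = "zz"),
    "unknown feature"
  )
})
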