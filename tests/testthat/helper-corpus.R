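# Shared synthetic fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# Strongly separated two-class corpus plus its feature matrix
separated_corpus <- function() {
  memo("sep", {
    corpus <- generate_corpus(n_per_class = 25L, seed = 101L)
    list(corpus = corpus, X = extract_feature_matrix(corpus))
  })
}

# Null-control corpus: both classes share one sequence model, labels carry
# no composition signal (nucleic-acid proportions equalized too)
null_corpus <- function() {
  memo("null", {
    M <- transition_matrix(0.5)
    corpus <- generate_corpus(
      n_per_class = 25L, phage_transition = M, euk_transition = M,
      dna_fraction = c(phage = 0.5, eukaryote = 0.5), seed = 202L
    )
    list(corpus = corpus, X = extract_feature_matrix(corpus))
  })
}

# Small planted-signal matrices for subset-search benchmarks
planted5 <- function() {
  memo("planted5",
       make_planted_features(n_per_class = 30L, n_informative = 2L,
                             n_noise = 3L, effect = 2.5, seed = 7L))
}

planted6 <- function() {
  memo("planted6",
       make_planted_features(n_per_class = 30L, n_informative = 2L,
                             n_noise = 4L, effect = 2.5, seed = 8L))
}

# Rank-based (Mann-Whitney) AUC oracle, independent of the ROC path
auc_rank_oracle <- function(scores, labels, positive = "phage") {
  pos <- if (is.numeric(labels)) labels == 1 else labels == positive
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive brute-force subset-search oracle
exhaustive_best <- function(X, y, algorithm = "knn", k = 5L, seed = 1L) {
  n <- ncol(X)
  best <- list(fitness = -Inf, subset = NULL)
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size)
    for (j in seq_len(ncol(combos))) {
      subset <- combos[, j]
      f <- as.numeric(evaluate_subset(X, y, subset,
        algorithm = algorithm, k = k, seed = seed
      ))
      if (f > best$fitness) best <- list(fitness = f, subset = subset)
    }
  }
  best
}
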