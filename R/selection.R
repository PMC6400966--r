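#' Create a fitness-evaluation cache
#'
#' Subset searches revisit the same feature subsets by construction; the
#' cache memoizes one cross-validation per (subset, algorithm,
#' hyperparameters) so each subset is evaluated exactly once.
#'
#' @return An environment usable as the `cache` argument of
#'   [evaluate_subset()] and the search functions.
#' @export
new_fitness_cache <- function() {
  new.env(parent = emptyenv())
}

subset_key <- function(subset_idx, algorithm, C, k) {
  paste0(algorithm, ";C=", C, ";k=", k, ";",
         paste(sort(subset_idx), collapse = ","))
}

canonical_subset <- function(subset, n_features) {
  if (is.logical(subset)) subset <- which(subset)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) stopf("feature subset must be non-empty")
  if (any(subset < 1L | subset > n_features)) {
    stopf("subset indices must lie in 1..%d", n_features)
  }
  subset
}

#' Cross-validated fitness of one feature subset
#'
#' Restricts the feature matrix to the subset's columns, runs
#' [cross_validate()] with the given algorithm and folds, and returns the
#' [fitness()] scalar. Results are memoized in `cache` keyed by the
#' canonical subset encoding plus the hyperparameters.
#'
#' @param X Raw feature matrix.
#' @param y Class labels.
#' @param subset Integer indices (or logical mask) over the columns of `X`.
#' @param algorithm,folds,seed,... Passed to [cross_validate()].
#' @param cache Optional cache from [new_fitness_cache()].
#' @return The fitness value, with the full `vh_cv_result` attached as
#'   attribute `"cv"`.
#' @export
evaluate_subset <- function(X, y, subset, algorithm = "knn", folds = 5L,
                            seed = 1L, cache = NULL, C = 1, k = 5L, ...) {
  subset <- canonical_subset(subset, ncol(X))
  key <- subset_key(subset, algorithm, C, k)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    return(cache[[key]])
  }
  cv <- cross_validate(X[, subset, drop = FALSE], y,
    algorithm = algorithm, folds = folds, seed = seed, C = C, k = k, ...
  )
  val <- structure(cv$fitness, cv = cv)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

selection_result <- function(best_subset, best_fitness, log, n_features,
                             method, seed, settings) {
  log <- log[!duplicated(log$subset), , drop = FALSE]
  log <- log[order(-log$fitness, log$subset), , drop = FALSE]
  rownames(log) <- NULL
  structure(
    list(
      best_subset = best_subset,
      best_fitness = best_fitness,
      log = log,
      n_features = n_features,
      method = method,
      seed = seed,
      settings = settings
    ),
    class = "vh_selection_result"
  )
}

#' @export
print.vh_selection_result <- function(x, ...) {
  cat(sprintf(
    "feature selection (%s): %d/%d features, fitness %.4f (%d subsets evaluated)\n",
    x$method, length(x$best_subset), x$n_features, x$best_fitness, nrow(x$log)
  ))
  invisible(x)
}

log_row <- function(subset, fitness_val) {
  cv <- attr(fitness_val, "cv")
  data.frame(
    subset = paste(subset, collapse = ","),
    size = length(subset),
    fitness = as.numeric(fitness_val),
    mean_mcc = cv$summary$mean_mcc,
    mean_auc = cv$summary$mean_auc,
    sd_mcc = cv$summary$sd_mcc,
    sd_auc = cv$summary$sd_auc,
    stringsAsFactors = FALSE
  )
}

#' Bottom-up feature-subset search
#'
#' Wrapper search designed for classifiers without usable coefficient-based
#' selectors (kNN, QDA). Phase 1 evaluates every subset of size 1 to
#' `init_max_len` exhaustively. Then, repeatedly: one of the `top_k`
#' highest-fitness subsets seen so far is picked uniformly at random as the
#' basis; all of its supersets with one extra feature are evaluated, and for
#' each new superset any of its same-size-as-basis subsets not yet evaluated
#' are evaluated too; the ranking is refreshed. The loop stops once the
#' membership of the top-`top_k` list has not changed for `patience`
#' consecutive rounds (or no unevaluated superset remains). The random basis
#' pick is what keeps the search from locking onto an early local optimum.
#'
#' @param X Raw feature matrix.
#' @param y Class labels.
#' @param algorithm,folds,C,k Passed to [evaluate_subset()].
#' @param top_k Size of the leaderboard the basis subset is drawn from
#'   (100 at full scale).
#' @param patience Consecutive rounds without leaderboard change required to
#'   stop (1000 at full scale); `patience = 0` returns the best subset of
#'   the initial enumeration.
#' @param init_max_len Maximum subset size of the exhaustive phase
#'   (default 3).
#' @param seed Integer seed (basis picks and fold construction).
#' @param cache Optional [new_fitness_cache()]; created internally if NULL.
#' @return A `vh_selection_result` with the best subset (integer column
#'   indices), its fitness, and the full evaluation log.
#' @export
bottom_up_search <- function(X, y, algorithm = "knn", folds = 5L,
                             C = 1, k = 5L,
                             top_k = 100L, patience = 1000L,
                             init_max_len = 3L, seed = 1L, cache = NULL) {
  if (top_k < 1L) stopf("top_k must be at least 1")
  if (patience < 0L) stopf("patience must be non-negative")
  n <- ncol(X)
  if (n < 1L) stopf("need at least one feature")
  if (is.null(cache)) cache <- new_fitness_cache()

  evaluated <- new.env(parent = emptyenv())
  log <- list()
  eval1 <- function(subset) {
    key <- paste(subset, collapse = ",")
    if (!is.null(evaluated[[key]])) return(invisible(NULL))
    val <- evaluate_subset(X, y, subset,
      algorithm = algorithm, folds = folds,
      seed = seed, cache = cache, C = C, k = k
    )
    evaluated[[key]] <- as.numeric(val)
    log[[length(log) + 1L]] <<- log_row(subset, val)
    invisible(NULL)
  }

  for (len in seq_len(min(init_max_len, n))) {
    combos <- combn(n, len)
    for (j in seq_len(ncol(combos))) eval1(combos[, j])
  }

  leaderboard <- function() {
    tab <- do.call(rbind, log)
    tab <- tab[!duplicated(tab$subset), , drop = FALSE]
    tab[order(-tab$fitness, tab$subset), , drop = FALSE]
  }

  with_seed(seed, {
    streak <- 0L
    prev_top <- head(leaderboard()$subset, top_k)
    while (streak < patience) {
      tab <- leaderboard()
      top <- head(tab, top_k)
      basis <- as.integer(strsplit(top$subset[sample.int(nrow(top), 1L)], ",")[[1L]])
      extensions <- setdiff(seq_len(n), basis)
      for (f in extensions) {
        superset <- sort(c(basis, f))
        eval1(superset)
        # evaluate missing same-size-as-basis subsets of the new superset
        subs <- combn(superset, length(basis))
        for (j in seq_len(ncol(subs))) eval1(subs[, j])
      }
      new_top <- head(leaderboard()$subset, top_k)
      if (identical(sort(new_top), sort(prev_top))) {
        streak <- streak + 1L
      } else {
        streak <- 0L
      }
      prev_top <- new_top
      # every subset evaluated: the leaderboard can never change again
      if (length(ls(evaluated)) >= 2^n - 1) break
    }
  })

  tab <- leaderboard()
  best <- as.integer(strsplit(tab$subset[1L], ",")[[1L]])
  selection_result(
    best, tab$fitness[1L], tab, n, "bottom-up", seed,
    list(top_k = top_k, patience = patience, init_max_len = init_max_len,
         algorithm = algorithm, C = C, k = k)
  )
}

#' Genetic-algorithm feature-subset search
#'
#' Evolves populations of binary inclusion vectors over the feature set with
#' tournament selection, two-point crossover and per-bit mutation. Each run
#' stops after `generations` generations or as soon as the population is
#' uniform; the whole procedure is repeated `repeats` times and the
#' best-fitness individual ever evaluated is returned. Empty individuals are
#' repaired by switching one random bit on.
#'
#' @inheritParams bottom_up_search
#' @param pop_size Number of individuals per generation (>= 2).
#' @param generations Generation cap per run (200 at full scale).
#' @param tournament_size Individuals drawn per tournament (default 3).
#' @param crossover_p Probability that a mated pair undergoes two-point
#'   crossover (default 0.5).
#' @param mutation_p Per-bit mutation probability; default `1/n_features`.
#' @param repeats Independent runs (default 5).
#' @return A `vh_selection_result`.
#' @export
ga_search <- function(X, y, algorithm = "knn", folds = 5L, C = 1, k = 5L,
                      pop_size = 100L, generations = 200L,
                      tournament_size = 3L, crossover_p = 0.5,
                      mutation_p = NULL, repeats = 5L,
                      seed = 1L, cache = NULL, init_population = NULL) {
  if (pop_size < 2L) stopf("pop_size must be at least 2")
  n <- ncol(X)
  if (is.null(mutation_p)) mutation_p <- 1 / n
  if (is.null(cache)) cache <- new_fitness_cache()

  log <- list()
  fit1 <- function(bits) {
    subset <- which(bits)
    val <- evaluate_subset(X, y, subset,
      algorithm = algorithm, folds = folds,
      seed = seed, cache = cache, C = C, k = k
    )
    log[[length(log) + 1L]] <<- log_row(subset, val)
    as.numeric(val)
  }
  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(n, 1L)] <- TRUE
    bits
  }

  best_bits <- NULL
  best_fit <- -Inf

  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      pop <- if (!is.null(init_population)) {
        lapply(init_population, function(b) repair(as.logical(b)))
      } else {
        lapply(seq_len(pop_size), function(i) repair(runif(n) < 0.5))
      }
      fits <- vapply(pop, fit1, numeric(1))
      gen <- 0L
      repeat {
        i <- which.max(fits)
        if (fits[i] > best_fit) {
          best_fit <- fits[i]
          best_bits <- pop[[i]]
        }
        uniform <- length(unique(vapply(pop, function(b) paste(as.integer(b), collapse = ""),
                                        character(1)))) == 1L
        if (uniform || gen >= generations) break
        # tournament selection
        sel <- lapply(seq_along(pop), function(j) {
          cand <- sample.int(length(pop), tournament_size, replace = TRUE)
          pop[[cand[which.max(fits[cand])]]]
        })
        # two-point crossover on consecutive pairs
        for (j in seq(1L, length(sel) - 1L, by = 2L)) {
          if (runif(1) < crossover_p && n >= 2L) {
            pts <- sort(sample.int(n, 2L))
            span <- pts[1L]:pts[2L]
            tmp <- sel[[j]][span]
            sel[[j]][span] <- sel[[j + 1L]][span]
            sel[[j + 1L]][span] <- tmp
          }
        }
        # per-bit mutation + repair
        pop <- lapply(sel, function(b) {
          flip <- runif(n) < mutation_p
          repair(xor(b, flip))
        })
        fits <- vapply(pop, fit1, numeric(1))
        gen <- gen + 1L
      }
    }
  })

  tab <- do.call(rbind, log)
  selection_result(
    which(best_bits), best_fit, tab, n, "genetic-algorithm", seed,
    list(pop_size = pop_size, generations = generations,
         tournament_size = tournament_size, crossover_p = crossover_p,
         mutation_p = mutation_p, repeats = repeats,
         algorithm = algorithm, C = C, k = k)
  )
}

#' ANOVA F-statistic per feature
#'
#' One-way ANOVA F between a binary label and each feature column; the
#' filter statistic behind `kbest` selection. Constant columns get F = 0.
#'
#' @param X Feature matrix.
#' @param y Two-class labels.
#' @return Numeric vector of F-values, one per column of `X`.
#' @export
anova_f <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  groups <- unique(y)
  n <- nrow(X)
  gm <- colMeans(X)
  ss_between <- 0
  ss_within <- 0
  for (g in groups) {
    Xi <- X[y == g, , drop = FALSE]
    mi <- colMeans(Xi)
    ss_between <- ss_between + nrow(Xi) * (mi - gm)^2
    ss_within <- ss_within + colSums(sweep(Xi, 2L, mi, "-")^2)
  }
  df1 <- length(groups) - 1L
  df2 <- n - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  f[!is.finite(f)] <- 0
  f
}

#' Embedded and filter feature selection
#'
#' The selector families used with the coefficient-bearing classifiers:
#' * `"lasso"` — L1-penalized logistic regression over the conventional
#'   grid of C values (powers of two, 2^-5 to 2^5); for each grid point the
#'   surviving nonzero-coefficient features are evaluated by
#'   cross-validated [fitness()] with an `lr` model and the best grid point
#'   wins.
#' * `"kbest"` — features ranked by [anova_f()]; each candidate k keeps the
#'   top-k features, evaluated by fitness with an `svc` model.
#' * `"rfe"` — recursive feature elimination: a linear SVC is refitted and
#'   the feature with the smallest absolute weight is dropped, one at a
#'   time, down to a single feature; each visited subset size is evaluated
#'   by fitness.
#'
#' @inheritParams bottom_up_search
#' @param method `"lasso"`, `"rfe"` or `"kbest"`.
#' @param C_grid Grid of C values for `lasso` (default `2^(-5:5)`).
#' @param k_grid Candidate subset sizes for `kbest`/`rfe`; default all of
#'   `1..ncol(X)`.
#' @param C Fixed C for the `svc`/`lr` models used in fitness evaluation.
#' @return A `vh_selection_result`.
#' @export
embedded_select <- function(X, y, method = c("lasso", "rfe", "kbest"),
                            folds = 5L, C = 1, C_grid = 2^(-5:5),
                            k_grid = NULL, seed = 1L, cache = NULL) {
  method <- match.arg(method)
  n <- ncol(X)
  if (is.null(k_grid)) k_grid <- seq_len(n)
  if (is.null(cache)) cache <- new_fitness_cache()
  y01 <- as_binary_labels(y, positive_of(y))
  std <- fit_standardization(X)
  Z <- standardize(X, std)

  candidates <- switch(method,
    lasso = {
      lapply(C_grid, function(Cg) {
        lambda <- 1 / (nrow(Z) * Cg)
        path <- exp(seq(log(lambda * 1000), log(lambda), length.out = 20L))
        path[20L] <- lambda
        g <- glmnet::glmnet(Z, y01,
          family = "binomial", alpha = 1, lambda = path,
          standardize = FALSE
        )
        cf <- if (length(g$lambda) > 1L) {
          as.numeric(coef(g, s = lambda))[-1L]
        } else {
          as.numeric(coef(g))[-1L]
        }
        list(subset = which(cf != 0), eval_algorithm = "lr", eval_C = Cg)
      })
    },
    kbest = {
      f <- anova_f(Z, y)
      ranked <- order(-f, seq_len(n))
      lapply(k_grid, function(kk) {
        list(subset = sort(ranked[seq_len(kk)]), eval_algorithm = "svc", eval_C = C)
      })
    },
    rfe = {
      remaining <- seq_len(n)
      path <- list(sort(remaining))
      while (length(remaining) > 1L) {
        w <- svc_weights(Z[, remaining, drop = FALSE], y01, C, seed)
        drop_i <- which.min(abs(w))
        remaining <- remaining[-drop_i]
        path[[length(path) + 1L]] <- sort(remaining)
      }
      keep <- vapply(path, length, integer(1)) %in% k_grid
      lapply(path[keep], function(s) {
        list(subset = s, eval_algorithm = "svc", eval_C = C)
      })
    }
  )

  candidates <- Filter(function(cand) length(cand$subset) > 0L, candidates)
  if (length(candidates) == 0L) stopf("no non-empty candidate subset produced")

  log <- list()
  fits <- vapply(candidates, function(cand) {
    val <- evaluate_subset(X, y, cand$subset,
      algorithm = cand$eval_algorithm, folds = folds, seed = seed,
      cache = cache, C = cand$eval_C, k = 5L
    )
    log[[length(log) + 1L]] <<- log_row(cand$subset, val)
    as.numeric(val)
  }, numeric(1))

  best_i <- which.max(fits)
  selection_result(
    candidates[[best_i]]$subset, fits[best_i], do.call(rbind, log), n,
    paste0("embedded-", method), seed,
    list(method = method, C_grid = C_grid, k_grid = k_grid, C = C)
  )
}

positive_of <- function(y) {
  classes <- sort(unique(as.character(y)))
  if (CLASS_PHAGE %in% classes) CLASS_PHAGE else classes[2L]
}

svc_weights <- function(Z, y01, C, seed) {
  yf <- factor(y01, levels = c(0L, 1L))
  fit <- with_seed(seed, e1071::svm(Z, yf,
    kernel = "linear", cost = C, scale = FALSE, type = "C-classification"
  ))
  as.numeric(t(fit$coefs) %*% fit$SV)
}

#' Write a feature-selection log as TSV
#'
#' @param result A `vh_selection_result`.
#' @param path Output path. Columns: subset (comma-joined indices), size,
#'   fitness, mean/SD of MCC and AUC.
#' @return Invisibly, `path`.
#' @export
write_selection_log <- function(result, path) {
  utils::write.table(result$log, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
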