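test_that("subset evaluation is memoized and rejects empty subsets", {
  pl <- planted5()
  cache <- new_fitness_cache()
  f1 <- evaluate_subset(pl$X, pl$y, c(1, 2), algorithm = "knn", cache = cache)
  keys <- ls(cache)
  expect_length(keys, 1L)
  # poison the cache entry: a second call must return it untouched (cache hit)
  cache[[keys]] <- structure(123, cv = attr(cache[[keys]], "cv"))
  f2 <- evaluate_subset(pl$X, pl$y, c(2, 1), algorithm = "knn", cache = cache)
  expect_equal(as.numeric(f2), 123)
  expect_error(evaluate_subset(pl$X, pl$y, integer(0)), "non-empty")
  expect_error(evaluate_subset(pl$X, pl$y, c(1, 99)), "1..5")
  # without poisoning, re-evaluation is exact
  expect_equal(as.numeric(f1),
               as.numeric(evaluate_subset(pl$X, pl$y, c(1, 2), algorithm = "knn")))
})

test_that("informative subsets outscore equal-size noise subsets on planted data", {
  pl <- planted5()
  f_inf <- evaluate_subset(pl$X, pl$y, pl$informative, algorithm = "knn", seed = 2)
  f_noise <- evaluate_subset(pl$X, pl$y, c(3, 4), algorithm = "knn", seed = 2)
  expect_gt(as.numeric(f_inf), as.numeric(f_noise))
})

test_that("bottom-up search matches the exhaustive oracle on a 5-feature universe", {
  pl <- planted5()
  res <- bottom_up_search(pl$X, pl$y,
    algorithm = "knn", k = 5,
    top_k = 5, patience = 3, init_max_len = 3, seed = 9
  )
  oracle <- exhaustive_best(pl$X, pl$y, algorithm = "knn", k = 5, seed = 9)
  expect_equal(res$best_fitness, oracle$fitness)
  expect_true(all(pl$informative %in% res$best_subset))
  # cache bound: never more evaluations than non-empty subsets
  expect_lte(nrow(res$log), 2^5 - 1)
  # the logged best is the max of the log (running maximum never drops)
  expect_equal(res$best_fitness, max(res$log$fitness))
  # re-evaluated best matches its logged value exactly (cache coherence)
  expect_equal(
    as.numeric(evaluate_subset(pl$X, pl$y, res$best_subset,
                               algorithm = "knn", k = 5, seed = 9)),
    res$best_fitness
  )
})

test_that("bottom-up with zero patience stops after the initial enumeration", {
  pl <- planted5()
  res <- bottom_up_search(pl$X, pl$y,
    algorithm = "knn", k = 5,
    top_k = 5, patience = 0, init_max_len = 2, seed = 9
  )
  expect_true(all(res$log$size <= 2))
  expect_equal(nrow(res$log), choose(5, 1) + choose(5, 2))
  expect_equal(res$best_fitness, max(res$log$fitness))
  expect_error(bottom_up_search(pl$X, pl$y, top_k = 0), "top_k")
  expect_error(bottom_up_search(pl$X, pl$y, patience = -1), "patience")
})

test_that("genetic algorithm reaches near-oracle fitness on a 6-feature universe", {
  pl <- planted6()
  cache <- new_fitness_cache()
  res <- ga_search(pl$X, pl$y,
    algorithm = "knn", k = 5,
    pop_size = 16, generations = 20, repeats = 5, seed = 10, cache = cache
  )
  oracle <- exhaustive_best(pl$X, pl$y, algorithm = "knn", k = 5, seed = 10)
  expect_gte(res$best_fitness, 0.95 * oracle$fitness)
  expect_lte(res$best_fitness, oracle$fitness + 1e-12)
})

test_that("a uniform initial population with no variation stops immediately", {
  pl <- planted6()
  opt <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res <- ga_search(pl$X, pl$y,
    algorithm = "knn", k = 5,
    pop_size = 4, generations = 50, repeats = 1,
    crossover_p = 0, mutation_p = 0, seed = 3,
    init_population = rep(list(opt), 4)
  )
  expect_identical(res$best_subset, which(opt))
  # only the initial population was ever evaluated
  expect_equal(nrow(res$log), 1L) # deduplicated: one unique subset
  expect_error(ga_search(pl$X, pl$y, pop_size = 1), "pop_size")
})

test_that("ANOVA F ranks planted features above pure noise", {
  pl <- planted5()
  f <- anova_f(pl$X, pl$y)
  expect_gt(min(f[pl$informative]), max(f[-pl$informative]))
  # constant features get F = 0, not NaN
  Xc <- cbind(pl$X, const = 1)
  expect_equal(unname(anova_f(Xc, pl$y)["const"]), 0)
})

test_that("embedded selectors honour their size contracts", {
  pl <- planted5()
  # kbest with k = n keeps everything
  res_all <- embedded_select(pl$X, pl$y, "kbest", k_grid = 5L, seed = 2)
  expect_identical(res_all$best_subset, 1:5)
  # rfe restricted to single-feature subsets returns exactly one feature
  res_one <- embedded_select(pl$X, pl$y, "rfe", k_grid = 1L, seed = 2)
  expect_length(res_one$best_subset, 1L)
  expect_true(res_one$best_subset %in% pl$informative)
})

test_that("lasso path recovers the planted features", {
  pl <- planted5()
  res <- embedded_select(pl$X, pl$y, "lasso",
                         C_grid = 2^(-5:2), seed = 2)
  expect_true(all(pl$informative %in% res$best_subset))
})

test_that("independent selection approaches agree on the planted features", {
  pl <- planted5()
  res_bu <- bottom_up_search(pl$X, pl$y,
    algorithm = "knn", k = 5, top_k = 5, patience = 2, seed = 4
  )
  res_kb <- embedded_select(pl$X, pl$y, "kbest", k_grid = 1:5, seed = 4)
  common <- intersect(res_bu$best_subset, res_kb$best_subset)
  expect_true(all(pl$informative %in% common))
})

test_that("selection logs serialize and carry coherent fitness values", {
  pl <- planted5()
  res <- bottom_up_search(pl$X, pl$y,
    algorithm = "knn", k = 5, top_k = 3, patience = 1, seed = 4
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_log(res, path)
  log <- read.delim(path, colClasses = c(subset = "character"))
  expect_equal(nrow(log), nrow(res$log))
  expect_equal(max(log$fitness), res$best_fitness)
  expect_false(any(duplicated(log$subset)))
})
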