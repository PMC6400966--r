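#' Feature-subset intersection randomization test
#'
#' Monte-Carlo null test for whether independently selected feature subsets
#' share more features than random subsets of the same sizes would. Each
#' repetition draws, for every given size, a uniform subset of the
#' universe without replacement, intersects all of them simultaneously and
#' records the intersection size; the estimated p-value is the fraction of
#' repetitions with intersection at least `threshold`.
#'
#' The default sizes are the eight selected-subset cardinalities of the
#' phage-versus-eukaryote classifiers (the two identical kNN subsets
#' counted once) over the 101-feature universe, for which the observed
#' two-feature overlap has null probability about 3e-3.
#'
#' @param subset_sizes Integer sizes of the subsets to draw.
#' @param universe_size Number of features in the universe (default 101).
#' @param threshold Observed common-feature count to test (default 2).
#' @param reps Monte-Carlo repetitions (default 1e6).
#' @param seed Integer seed.
#' @return Object of class `vh_intersection_test`: list with `p_value`
#'   (P(size >= threshold)), `mean_size`, `expected_size` (closed form
#'   `universe_size * prod(subset_sizes/universe_size)`), `distribution`
#'   (named count table of intersection sizes), `threshold`, `reps`, `seed`.
#' @examples
#' intersection_test(c(3, 3), universe_size = 4, reps = 1000, seed = 1)
#' @export
intersection_test <- function(subset_sizes = c(49L, 17L, 37L, 28L, 32L, 95L, 58L, 60L),
                              universe_size = 101L, threshold = 2L,
                              reps = 1e6, seed = 1L) {
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes < 0L) || any(subset_sizes > universe_size)) {
    stopf("subset sizes must lie in 0..universe_size")
  }
  if (threshold < 0L) stopf("threshold must be non-negative")
  if (reps < 1) stopf("reps must be at least 1")
  reps <- as.integer(reps)
  n_sets <- length(subset_sizes)

  sizes_tab <- with_seed(seed, {
    counts <- integer(reps)
    if (any(subset_sizes == 0L)) {
      # empty subset forces an empty intersection every time
      counts
    } else {
      for (i in seq_len(reps)) {
        drawn <- unlist(lapply(subset_sizes, function(sz) {
          sample.int(universe_size, sz)
        }), use.names = FALSE)
        counts[i] <- sum(tabulate(drawn, universe_size) == n_sets)
      }
      counts
    }
  })

  structure(
    list(
      p_value = mean(sizes_tab >= threshold),
      mean_size = mean(sizes_tab),
      expected_size = universe_size * prod(subset_sizes / universe_size),
      distribution = table(sizes_tab),
      subset_sizes = subset_sizes,
      universe_size = universe_size,
      threshold = threshold,
      reps = reps,
      seed = seed
    ),
    class = "vh_intersection_test"
  )
}

#' @export
print.vh_intersection_test <- function(x, ...) {
  cat(sprintf(
    "intersection randomization test: %d subsets over %d features, %s reps\n  P(common >= %d) = %.3g\n  mean intersection %.4g (closed form %.4g)\n",
    length(x$subset_sizes), x$universe_size, format(x$reps, big.mark = ","),
    x$threshold, x$p_value, x$mean_size, x$expected_size
  ))
  invisible(x)
}

#' Write an intersection-test report as JSON
#'
#' @param x A `vh_intersection_test`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intersection_report <- function(x, path) {
  jsonlite::write_json(
    list(
      p_value = x$p_value,
      mean_size = x$mean_size,
      expected_size = x$expected_size,
      distribution = as.list(setNames(as.integer(x$distribution),
                                      names(x$distribution))),
      subset_sizes = x$subset_sizes,
      universe_size = x$universe_size,
      threshold = x$threshold,
      reps = x$reps,
      seed = x$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Number of non-empty feature subsets, exactly
#'
#' \eqn{\sum_{k=1}^{n} \binom{n}{k} = 2^n - 1}, computed in exact
#' arbitrary-precision integer arithmetic (decimal digit vector, so no
#' floating-point overflow up to n = 1000 and beyond). For 101 features
#' this is about 2.54e30 subsets; adding tetranucleotides (357 features)
#' pushes it to about 2.94e107 — the combinatorial wall that makes
#' heuristic subset search unavoidable.
#'
#' @param n Number of features (non-negative integer).
#' @return Object of class `vh_bigint`; use [format()]/[as.character()] for
#'   the exact decimal digits and [as.numeric()] for a double
#'   approximation.
#' @examples
#' count_nonempty_subsets(2) # 3
#' as.numeric(count_nonempty_subsets(101))
#' @export
count_nonempty_subsets <- function(n) {
  if (length(n) != 1L || n < 0 || n != as.integer(n)) {
    stopf("n must be a single non-negative integer")
  }
  # little-endian decimal digits of 2^n, then subtract 1
  digits <- 1L
  for (i in seq_len(n)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] + carry
      digits[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  j <- 1L
  while (digits[j] == 0L) {
    digits[j] <- 9L
    j <- j + 1L
  }
  digits[j] <- digits[j] - 1L
  while (length(digits) > 1L && digits[length(digits)] == 0L) {
    digits <- digits[-length(digits)]
  }
  structure(list(digits = digits), class = "vh_bigint")
}

#' @export
format.vh_bigint <- function(x, ...) {
  paste(rev(x$digits), collapse = "")
}

#' @export
as.character.vh_bigint <- function(x, ...) format(x)

#' @export
as.double.vh_bigint <- function(x, ...) {
  d <- rev(x$digits)
  # mantissa from the leading digits, exponent from the length
  mant <- as.numeric(paste(head(d, 17L), collapse = ""))
  mant * 10^(length(d) - min(length(d), 17L))
}

#' @export
print.vh_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Pearson correlation between two feature-weight vectors
#'
#' Compares the per-feature weights assigned by two trained models or
#' selection runs: Pearson r with a two-tailed p-value. A positive r means
#' the two approaches agree on which features push towards phages.
#'
#' @param w1,w2 Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return List with elements `r` and `p`.
#' @examples
#' weight_correlation(c(1, 2, 3, 4), c(1, 2, 3, 100))
#' @export
weight_correlation <- function(w1, w2) {
  if (length(w1) != length(w2)) stopf("weight vectors must have equal length")
  if (length(w1) < 3L) stopf("need at least 3 weights")
  if (sd_pop(w1) == 0 || sd_pop(w2) == 0) {
    stopf("weight vectors must have non-zero variance")
  }
  ct <- cor.test(w1, w2, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
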