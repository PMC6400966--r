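#' Class and host-group labels from a host lineage string
#'
#' Maps a semicolon-delimited host taxonomic path, rooted at a
#' superkingdom, to the binary class: hosts rooted at Bacteria or Archaea
#' give phages, hosts rooted at Eukaryota give eukaryote-infecting viruses.
#' Eukaryote-infecting viruses additionally get a host group: seed plants
#' (lineage contains Spermatophyta), vertebrates (Vertebrata), arthropods
#' (Arthropoda), or other.
#'
#' @param lineage Character vector of semicolon-delimited lineage strings.
#' @return Data frame with columns `class` and `group` (`NA` group for
#'   phages). Unrecognized or empty lineages raise an error.
#' @examples
#' label_from_lineage("Bacteria; Proteobacteria; Gammaproteobacteria")
#' label_from_lineage("Eukaryota; Metazoa; Chordata; Craniata; Vertebrata")
#' @export
label_from_lineage <- function(lineage) {
  if (length(lineage) == 0L) stopf("lineage must be non-empty")
  parts <- lapply(strsplit(as.character(lineage), ";"), trimws)
  root <- vapply(parts, function(p) if (length(p) && nzchar(p[1L])) p[1L] else NA_character_,
                 character(1))
  bad <- is.na(root) | !root %in% c("Bacteria", "Archaea", "Eukaryota")
  if (any(bad)) {
    stopf("unrecognized lineage root(s): %s",
          paste(unique(ifelse(is.na(root[bad]), "<empty>", root[bad])), collapse = ", "))
  }
  cls <- ifelse(root == "Eukaryota", CLASS_EUK, CLASS_PHAGE)
  group <- vapply(seq_along(parts), function(i) {
    if (cls[i] != CLASS_EUK) return(NA_character_)
    p <- parts[[i]]
    if ("Spermatophyta" %in% p) "seed-plant"
    else if ("Vertebrata" %in% p) "vertebrate"
    else if ("Arthropoda" %in% p) "arthropod"
    else "other"
  }, character(1))
  data.frame(class = cls, group = group, stringsAsFactors = FALSE)
}

#' Exponential per-lineage sampling probability
#'
#' Probability that the i-th virus of a lineage is drawn into the
#' cross-validation set: \eqn{P(v_i) = e^{-i^\alpha}}. The decay makes large
#' lineages contribute only a few representatives, down-weighting redundant
#' near-identical genomes; the exponent calibrated for the classifier
#' corpus is 0.217.
#'
#' @param i Positive integer rank(s) of the virus within its lineage.
#' @param alpha Positive decay exponent (default 0.217).
#' @return Probabilities in `(0, 1)`.
#' @examples
#' sampling_probability(1) # exp(-1), for any alpha
#' @export
sampling_probability <- function(i, alpha = 0.217) {
  if (any(i < 1) || any(i != as.integer(i))) stopf("i must be a positive integer")
  if (alpha <= 0) stopf("alpha must be positive")
  exp(-i^alpha)
}

expected_cv_count <- function(lineage_sizes, alpha) {
  sum(vapply(lineage_sizes, function(s) sum(sampling_probability(seq_len(s), alpha)),
             numeric(1)))
}

#' Calibrate the sampling exponent for a target cross-validation count
#'
#' Finds the exponent alpha for which the expected number of viruses drawn
#' by [sampling_probability()] across the given lineages,
#' \eqn{\sum_l \sum_{i=1}^{n_l} e^{-i^\alpha}}, is closest to
#' `target_count` (squared-error scalar minimization). Used to balance the
#' abundant eukaryote-infecting class against the phages.
#'
#' @param lineage_sizes Integer vector: number of viruses in each lineage.
#' @param target_count Desired expected number of sampled viruses.
#' @param interval Search interval for alpha.
#' @return The calibrated alpha. If the target is unreachable within
#'   `interval` the nearest boundary is returned with a warning.
#' @export
optimize_alpha <- function(lineage_sizes, target_count,
                           interval = c(0.01, 10)) {
  if (any(lineage_sizes < 1)) stopf("lineage sizes must be positive")
  if (target_count <= 0) stopf("target_count must be positive")
  obj <- function(a) (expected_cv_count(lineage_sizes, a) - target_count)^2
  opt <- optimize(obj, interval = interval)
  # E[count] is monotone decreasing in alpha; check reachability at the ends
  lo <- expected_cv_count(lineage_sizes, interval[1L])
  hi <- expected_cv_count(lineage_sizes, interval[2L])
  if (target_count > lo || target_count < hi) {
    warning(sprintf(
      "target %g outside achievable range [%.4g, %.4g]; returning boundary alpha",
      target_count, hi, lo
    ), call. = FALSE)
    return(if (target_count > lo) interval[1L] else interval[2L])
  }
  opt$minimum
}

#' Lineage-aware cross-validation/test partition
#'
#' Splits a labeled virus table into a 5-fold cross-validation set and a
#' held-out test set the way redundancy-aware host classification requires:
#' within each class, viruses are sorted alphabetically by host lineage
#' (then id) so near-identical genomes stay adjacent; every
#' `round(1/test_fraction)`-th lineage block goes to the test set; among the
#' remaining cross-validation candidates, phages are all kept while the
#' (more abundant) eukaryote-infecting viruses are thinned per lineage with
#' [sampling_probability()]; finally each class's cross-validation members
#' are cut, still in lineage order, into `n_folds` contiguous folds of
#' near-equal size.
#'
#' @param viruses Data frame with columns `id` and `host_lineage`
#'   (columns `class`/`group` are recomputed from the lineage). If a
#'   `genome_type` column is present (e.g. dsDNA, ssRNA), records are
#'   additionally stratified by it: sorting and test-lineage selection
#'   happen within each genome type, so both the cross-validation and the
#'   test set contain every genome-type group.
#' @param test_fraction Approximate fraction of lineages held out (default
#'   0.2).
#' @param alpha Sampling exponent for the eukaryote-infecting class
#'   (default 0.217; see [optimize_alpha()]).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the per-lineage Bernoulli draws.
#' @return Object of class `vh_partition`: data frame with columns `id`,
#'   `class`, `group`, `split` (`"cv1"`..`"cv5"`, `"test"`, or `"unused"`
#'   for thinned-out records), plus attributes `alpha` and `seed`.
#' @export
partition_viruses <- function(viruses, test_fraction = 0.2, alpha = 0.217,
                              n_folds = 5L, seed = 1L) {
  need <- c("id", "host_lineage")
  if (!all(need %in% names(viruses))) {
    stopf("viruses must have columns %s", paste(need, collapse = ", "))
  }
  lab <- label_from_lineage(viruses$host_lineage)
  df <- data.frame(
    id = viruses$id,
    host_lineage = viruses$host_lineage,
    class = lab$class,
    group = lab$group,
    split = NA_character_,
    stringsAsFactors = FALSE
  )
  if (length(unique(df$class)) < 2L) {
    stopf("both classes must be present to partition")
  }
  every <- max(2L, as.integer(round(1 / test_fraction)))
  genome_type <- if ("genome_type" %in% names(viruses)) {
    as.character(viruses$genome_type)
  } else {
    rep("", nrow(df))
  }
  # block key: lineage within its genome-type stratum
  block <- paste(genome_type, df$host_lineage, sep = "\r")

  with_seed(seed, {
    for (cl in c(CLASS_PHAGE, CLASS_EUK)) {
      idx <- which(df$class == cl)
      idx <- idx[order(genome_type[idx], df$host_lineage[idx], df$id[idx])]
      # every `every`-th lineage block, counted within each genome-type
      # stratum, goes to the test set
      blocks <- unique(block[idx])
      block_gt <- sub("\r.*$", "", blocks)
      rank_in_stratum <- stats::ave(seq_along(blocks), block_gt,
                                    FUN = seq_along)
      test_blocks <- blocks[rank_in_stratum %% every == 0L]
      is_test <- block[idx] %in% test_blocks
      df$split[idx[is_test]] <- "test"
      cv_idx <- idx[!is_test]
      if (cl == CLASS_EUK) {
        # thin redundant lineages: keep the i-th member with P = exp(-i^alpha)
        keep <- logical(length(cv_idx))
        for (lin in unique(block[cv_idx])) {
          members <- which(block[cv_idx] == lin)
          p <- sampling_probability(seq_along(members), alpha)
          keep[members] <- runif(length(members)) < p
        }
        df$split[cv_idx[!keep]] <- "unused"
        cv_idx <- cv_idx[keep]
      }
      if (length(cv_idx) < n_folds) {
        stopf("class %s has %d cross-validation members; need at least %d",
              cl, length(cv_idx), n_folds)
      }
      # contiguous fold cut preserves lineage adjacency
      fold <- sort(rep_len(seq_len(n_folds), length(cv_idx)))
      df$split[cv_idx] <- paste0("cv", fold)
    }
  })

  structure(
    df[, c("id", "class", "group", "split")],
    alpha = alpha, seed = seed, n_folds = n_folds,
    class = c("vh_partition", "data.frame")
  )
}

#' Fold assignment vector from a partition
#'
#' @param partition A `vh_partition`.
#' @param ids Record ids to look up (cross-validation members only).
#' @return Integer fold indices aligned to `ids`.
#' @export
partition_folds <- function(partition, ids) {
  m <- match(ids, partition$id)
  if (anyNA(m)) stopf("unknown id(s): %s", paste(ids[is.na(m)], collapse = ", "))
  split <- partition$split[m]
  if (!all(grepl("^cv[0-9]+$", split))) {
    stopf("all requested ids must belong to the cross-validation set")
  }
  as.integer(sub("^cv", "", split))
}

#' Write or read a partition table
#'
#' @param partition A `vh_partition`.
#' @param path TSV path.
#' @return Invisibly `path` ([write_partition()]); the partition data frame
#'   ([read_partition()]).
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
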