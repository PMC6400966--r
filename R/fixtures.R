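#' First-order Markov transition matrix with a GC bias
#'
#' Convenience constructor for the class-conditional sequence models used
#' by [generate_corpus()]: every row assigns probability `gc` to G+C
#' (split equally) and `1 - gc` to A+T, and rows following C can
#' additionally deplete the CpG-like C->G step by `cg_depletion`,
#' redistributing the mass to C->A/C->T. The depletion plants a
#' dinucleotide-level signal that only the relative-frequency features can
#' see, mimicking the CpG suppression typical of many eukaryotic hosts.
#'
#' @param gc Stationary G+C content in `(0, 1)`.
#' @param cg_depletion Fraction of the C->G probability removed (0 = none).
#' @return A 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transition_matrix <- function(gc = 0.5, cg_depletion = 0) {
  if (gc <= 0 || gc >= 1) stopf("gc must lie strictly between 0 and 1")
  if (cg_depletion < 0 || cg_depletion > 1) stopf("cg_depletion must lie in [0, 1]")
  row <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  M <- matrix(rep(row, 4L), nrow = 4L, byrow = TRUE,
              dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
  if (cg_depletion > 0) {
    removed <- M["C", "G"] * cg_depletion
    M["C", "G"] <- M["C", "G"] - removed
    M["C", c("A", "T")] <- M["C", c("A", "T")] + removed / 2
  }
  M
}

markov_sequence <- function(length, transition) {
  # stationary-ish start: draw the first base from the column means
  start_p <- colMeans(transition)
  cum <- t(apply(transition, 1L, cumsum))
  out <- integer(length)
  out[1L] <- findInterval(runif(1), cumsum(start_p)) + 1L
  u <- runif(length - 1L)
  for (i in seq_len(length - 1L)) {
    out[i + 1L] <- findInterval(u[i], cum[out[i], ]) + 1L
  }
  paste(NUCLEOTIDES[pmin(out, 4L)], collapse = "")
}

#' Generate a synthetic two-class viral corpus
#'
#' Seeded generator of "phage-like" versus "eukaryote-like" genomes so the
#' entire pipeline (feature extraction, partitioning, training, fragment
#' simulation) can run without downloads. Sequences are drawn from
#' class-conditional first-order Markov chains — first-order structure so
#' that dinucleotide-level signal exists for the relative-frequency
#' features to detect — with per-class GC bias, nucleic-acid proportions
#' and synthetic host lineages (superkingdom; family-like; species-like)
#' spread over a configurable number of lineages per class.
#'
#' @param n_per_class Records per class (default 50); set the two classes
#'   apart or together via the transition matrices.
#' @param length_range Min/max sequence length (uniform; default
#'   2000-4000).
#' @param phage_transition,euk_transition Row-stochastic 4x4 transition
#'   matrices (defaults: GC 0.55 vs 0.40 with CpG depletion 0.5 for the
#'   eukaryote-like class).
#' @param dna_fraction Named vector: probability that a record of each
#'   class is DNA rather than RNA (default phage 0.9, eukaryote 0.5).
#' @param lineages_per_class Number of synthetic host lineages per class
#'   (default 5).
#' @param imbalance Multiplier on the eukaryote-class count (default 1;
#'   e.g. 4 mimics the natural abundance of eukaryote-infecting viruses).
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @return Data frame with columns `id`, `residues`, `nucleic_acid`,
#'   `host_lineage`, `class`.
#' @export
generate_corpus <- function(n_per_class = 50L,
                            length_range = c(2000L, 4000L),
                            phage_transition = transition_matrix(0.55),
                            euk_transition = transition_matrix(0.40, cg_depletion = 0.5),
                            dna_fraction = c(phage = 0.9, eukaryote = 0.5),
                            lineages_per_class = 5L,
                            imbalance = 1,
                            seed = 1L) {
  check_transition <- function(M, what) {
    if (!is.matrix(M) || !all(dim(M) == 4L) || any(M < 0) ||
        any(abs(rowSums(M) - 1) > 1e-8)) {
      stopf("%s must be a 4x4 row-stochastic matrix", what)
    }
  }
  check_transition(phage_transition, "phage_transition")
  check_transition(euk_transition, "euk_transition")
  if (length_range[1L] < 10L) stopf("sequences must be at least 10 bases")

  n_phage <- as.integer(n_per_class)
  n_euk <- as.integer(round(n_per_class * imbalance))

  phage_roots <- c("Bacteria", "Archaea")
  euk_tags <- c("Spermatophyta", "Vertebrata", "Arthropoda", "Fungi")

  with_seed(seed, {
    make_class <- function(n, class, transition, p_dna) {
      lineage_pool <- if (class == CLASS_PHAGE) {
        sprintf(
          "%s; Phylum_%02d; Family_%02d",
          sample(phage_roots, lineages_per_class, replace = TRUE),
          seq_len(lineages_per_class), seq_len(lineages_per_class)
        )
      } else {
        sprintf(
          "Eukaryota; Clade_%02d; %s; Species_%02d",
          seq_len(lineages_per_class),
          sample(euk_tags, lineages_per_class, replace = TRUE),
          seq_len(lineages_per_class)
        )
      }
      lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
      data.frame(
        id = sprintf("%s_%03d", ifelse(class == CLASS_PHAGE, "PH", "EU"), seq_len(n)),
        residues = vapply(lens, markov_sequence, character(1), transition = transition),
        nucleic_acid = ifelse(runif(n) < p_dna, "DNA", "RNA"),
        host_lineage = sample(lineage_pool, n, replace = TRUE),
        class = class,
        stringsAsFactors = FALSE
      )
    }
    rbind(
      make_class(n_phage, CLASS_PHAGE, phage_transition, dna_fraction[["phage"]]),
      make_class(n_euk, CLASS_EUK, euk_transition, dna_fraction[["eukaryote"]])
    )
  })
}

#' Train a demonstration classifier on a synthetic corpus
#'
#' Convenience wrapper for examples and quick starts: generates the default
#' synthetic corpus, extracts features and trains the requested classifier
#' on all records. The result is a fully usable model for the prediction
#' interfaces (including the command line), built on demand so no binary
#' model artifact needs to ship with the package.
#'
#' @param algorithm `"lr"`, `"knn"`, `"qda"` or `"svc"`.
#' @param n_per_class Synthetic records per class (default 25).
#' @param seed Integer seed for corpus generation and training.
#' @return A `vh_model`.
#' @examples
#' \donttest{
#' m <- demo_model("lr", n_per_class = 10)
#' predict(m, extract_features(paste(rep("ACGT", 100), collapse = ""), "DNA"))
#' }
#' @export
demo_model <- function(algorithm = "lr", n_per_class = 25L, seed = 1L) {
  corpus <- generate_corpus(n_per_class = n_per_class, seed = seed)
  X <- extract_feature_matrix(corpus)
  train_classifier(X, corpus$class, algorithm = algorithm, seed = seed)
}

#' Planted-signal feature matrix for selection benchmarks
#'
#' Builds a small two-class feature matrix in which the first
#' `n_informative` columns carry a mean shift of `effect` standard
#' deviations between the classes and the remaining `n_noise` columns are
#' pure standard-normal noise. Used to verify that subset searches recover
#' the informative features.
#'
#' @param n_per_class Samples per class.
#' @param n_informative Number of signal-bearing features.
#' @param n_noise Number of noise features.
#' @param effect Class mean separation in SD units (default 2).
#' @param seed Integer seed.
#' @return List with `X` (matrix, columns `inf1..`, `noise1..`), `y`
#'   (labels) and `informative` (indices of the planted columns).
#' @export
make_planted_features <- function(n_per_class = 30L, n_informative = 2L,
                                  n_noise = 3L, effect = 2, seed = 1L) {
  n <- 2L * n_per_class
  y <- rep(c(CLASS_PHAGE, CLASS_EUK), each = n_per_class)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * (n_informative + n_noise)), nrow = n)
    shift <- rep(c(effect / 2, -effect / 2), each = n_per_class)
    for (j in seq_len(n_informative)) X[, j] <- X[, j] + shift
    colnames(X) <- c(
      paste0("inf", seq_len(n_informative)),
      paste0("noise", seq_len(n_noise))
    )
    list(X = X, y = y, informative = seq_len(n_informative))
  })
}
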