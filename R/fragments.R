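#' Simulate metagenomic sequence fragments
#'
#' Draws fragments emulating reads/contigs from a corpus of source
#' sequences. A source of length S is chosen with probability proportional
#' to the number of possible windows, S - s + 1 (sources shorter than the
#' fragment length are excluded); the start is uniform over the valid
#' offsets; each position is then substituted independently with
#' probability `r` by a base drawn uniformly from the three alternatives
#' (a substituted position never keeps its original base). Fragments are
#' drawn with replacement and never wrap around sequence ends. Ambiguous
#' bases inside a window are kept as-is; the feature extractor skips the
#' affected k-mer windows downstream.
#'
#' The conventional evaluation sweep uses fragment lengths 100, 250, 500,
#' 1000, 3000, 10000 and substitution rates 0 and 0.02.
#'
#' @param corpus Data frame with columns `id` and `residues` (extra columns
#'   such as `nucleic_acid` are carried through to the output).
#' @param s Fragment length (single positive integer).
#' @param r Substitution rate in `[0, 1]` (default 0).
#' @param n_fragments Number of fragments to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `id` (fragment id), `source_id`, `start`
#'   (0-based offset), `n_substituted`, `residues`, plus any carried
#'   metadata columns of the source record.
#' @export
simulate_fragments <- function(corpus, s, r = 0, n_fragments = 1L, seed = 1L) {
  if (length(s) != 1L || s < 1L || s != as.integer(s)) {
    stopf("s must be a single positive integer")
  }
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stopf("substitution rate r must lie in [0, 1]")
  }
  if (!all(c("id", "residues") %in% names(corpus))) {
    stopf("corpus must have columns id and residues")
  }
  S <- nchar(corpus$residues)
  weights <- pmax(S - s + 1L, 0L)
  if (all(weights == 0L)) {
    stopf("no source sequence is at least %d bases long", s)
  }

  carried <- setdiff(names(corpus), c("id", "residues"))
  with_seed(seed, {
    src <- sample.int(nrow(corpus), n_fragments, replace = TRUE, prob = weights)
    start <- vapply(src, function(i) {
      sample.int(S[i] - s + 1L, 1L) - 1L
    }, integer(1))
    frags <- substr(corpus$residues[src], start + 1L, start + s)
    n_sub <- integer(n_fragments)
    if (r > 0) {
      for (j in seq_len(n_fragments)) {
        hit <- which(runif(s) < r)
        if (length(hit) > 0L) {
          chars <- strsplit(frags[j], "", fixed = TRUE)[[1L]]
          chars[hit] <- vapply(chars[hit], function(b) {
            alt <- setdiff(NUCLEOTIDES, b)
            alt[sample.int(length(alt), 1L)]
          }, character(1))
          frags[j] <- paste(chars, collapse = "")
          n_sub[j] <- length(hit)
        }
      }
    }
    out <- data.frame(
      id = sprintf("%s_frag%d_s%d_r%g", corpus$id[src], seq_len(n_fragments), s, r),
      source_id = corpus$id[src],
      start = start,
      n_substituted = n_sub,
      residues = frags,
      stringsAsFactors = FALSE
    )
    for (col in carried) out[[col]] <- corpus[[col]][src]
    out
  })
}

#' Write simulated fragments as FASTA plus a manifest
#'
#' Headers encode source id, start offset, fragment length and substitution
#' count; the companion TSV manifest carries the same fields as columns.
#'
#' @param fragments Data frame from [simulate_fragments()].
#' @param fasta_path,manifest_path Output paths (`manifest_path` optional).
#' @return Invisibly, `fasta_path`.
#' @export
write_fragments <- function(fragments, fasta_path, manifest_path = NULL) {
  headers <- sprintf(
    "%s source=%s start=%d nsub=%d",
    fragments$id, fragments$source_id, fragments$start, fragments$n_substituted
  )
  seqs <- Biostrings::BStringSet(setNames(fragments$residues, headers))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(manifest_path)) {
    utils::write.table(
      fragments[, setdiff(names(fragments), "residues")],
      manifest_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(fasta_path)
}

#' Fragment-length/substitution-rate evaluation sweep
#'
#' For every combination of fragment length and substitution rate,
#' simulates fragments from a labeled corpus, scores them with a trained
#' model and records the AUC — the fragment-level benchmark showing how
#' classification quality degrades with fragment length.
#'
#' @param corpus Labeled corpus (columns `id`, `residues`, `nucleic_acid`,
#'   `class`).
#' @param model A `vh_model`.
#' @param lengths Fragment lengths to test (default the conventional sweep).
#' @param rates Substitution rates to test (default 0 and 0.02).
#' @param n_fragments Fragments per combination.
#' @param seed Integer seed.
#' @return Data frame with columns `s`, `r`, `n`, `auc`.
#' @export
fragment_benchmark <- function(corpus, model,
                               lengths = c(100L, 250L, 500L, 1000L, 3000L, 10000L),
                               rates = c(0, 0.02),
                               n_fragments = 200L, seed = 1L) {
  if (!"class" %in% names(corpus)) stopf("corpus must carry a class column")
  grid <- expand.grid(s = lengths, r = rates)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$s[i]; r <- grid$r[i]
    if (all(nchar(corpus$residues) < s)) return(NULL)
    frags <- simulate_fragments(corpus, s = s, r = r,
                                n_fragments = n_fragments,
                                seed = seed + i)
    X <- extract_feature_matrix(frags)
    p <- predict_proba(model, X)[, unname(model$classes["positive"])]
    labels <- frags$class
    if (length(unique(labels)) < 2L) return(NULL)
    data.frame(s = s, r = r, n = nrow(frags),
               auc = auc(p, labels, positive = unname(model$classes["positive"])))
  })
  do.call(rbind, res)
}
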