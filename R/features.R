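#' The 101-feature composition schema
#'
#' Every sequence is represented by the same ordered vector of 101 features:
#' 4 mononucleotide absolute frequencies (`f_A` ... `f_T`), 16 dinucleotide
#' absolute frequencies (`f_AA` ... `f_TT`, lexicographic), 16 relative
#' dinucleotide frequencies (`rho_AA` ... `rho_TT`), 64 relative
#' trinucleotide frequencies (`gamma_AAA` ... `gamma_TTT`), and finally the
#' nucleic-acid indicator (`nucleic_acid`, +1 for DNA, -1 for RNA). All
#' frequencies are computed on a single strand; reverse-complement
#' symmetrization is deliberately not applied.
#'
#' @return Character vector of length 101 with the canonical feature names,
#'   in the fixed order used by every function in the package.
#' @examples
#' length(feature_schema())
#' head(feature_schema())
#' @export
feature_schema <- function() {
  di <- Biostrings::mkAllStrings(NUCLEOTIDES, 2)
  tri <- Biostrings::mkAllStrings(NUCLEOTIDES, 3)
  c(
    paste0("f_", NUCLEOTIDES),
    paste0("f_", di),
    paste0("rho_", di),
    paste0("gamma_", tri),
    "nucleic_acid"
  )
}

# Uppercase, strip whitespace, map U to T. Validates the residue alphabet
# (IUPAC nucleotide codes); anything else is an error.
normalize_residues <- function(residues) {
  if (length(residues) != 1L || is.na(residues) || !nzchar(residues)) {
    stopf("residues must be a single non-empty string")
  }
  x <- toupper(gsub("[[:space:]]", "", residues))
  x <- chartr("U", "T", x)
  letters <- unique(strsplit(x, "", fixed = TRUE)[[1L]])
  iupac <- c(NUCLEOTIDES, "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
  bad <- setdiff(letters, iupac)
  if (length(bad) > 0L) {
    stopf("invalid residue character(s): %s", paste(bad, collapse = ", "))
  }
  x
}

#' Relative dinucleotide frequency (composition odds ratio)
#'
#' The odds-ratio-style statistic \eqn{\rho_{XY} = f_{XY} / (f_X f_Y)}:
#' the observed dinucleotide frequency divided by its expectation under
#' independent mononucleotide composition. Values near 1 indicate no
#' dinucleotide-level bias. When the denominator is zero (a component base
#' absent from the sequence) the statistic is defined as 0 so that feature
#' vectors stay finite for low-complexity inputs.
#'
#' @param f_xy Absolute dinucleotide frequency, in `[0, 1]`.
#' @param f_x,f_y Absolute mononucleotide frequencies of the two component
#'   bases, in `[0, 1]`.
#' @return A single non-negative number.
#' @examples
#' relative_dinucleotide_frequency(2 / 3, 1 / 2, 1 / 2) # "ACAC": 8/3
#' @export
relative_dinucleotide_frequency <- function(f_xy, f_x, f_y) {
  check_freq(c(f_xy = f_xy, f_x = f_x, f_y = f_y))
  denom <- f_x * f_y
  if (denom == 0) return(0)
  f_xy / denom
}

#' Relative trinucleotide frequency
#'
#' The third-order composition statistic
#' \eqn{\gamma_{XYZ} = (f_{XYZ} f_X f_Y f_Z) / (f_{XY} f_{YZ} f_{XNZ})},
#' which corrects the observed trinucleotide frequency for all first- and
#' second-order effects, including the gapped dinucleotide \eqn{f_{XNZ}}
#' (first and third base fixed, any middle base). Defined as 0 whenever any
#' denominator factor is 0.
#'
#' @param f_xyz Absolute trinucleotide frequency.
#' @param f_xy,f_yz Absolute frequencies of the two embedded dinucleotides.
#' @param f_xnz Gapped frequency: 3-mers with the given first and third base.
#' @param f_x,f_y,f_z Mononucleotide frequencies of the component bases.
#' @return A single non-negative number.
#' @examples
#' # "ACGACG": f_ACG = 1/2, f_A = f_C = f_G = 1/3, f_AC = f_CG = 2/5, f_ANG = 1/2
#' relative_trinucleotide_frequency(1 / 2, 2 / 5, 2 / 5, 1 / 2, 1 / 3, 1 / 3, 1 / 3)
#' @export
relative_trinucleotide_frequency <- function(f_xyz, f_xy, f_yz, f_xnz,
                                             f_x, f_y, f_z) {
  check_freq(c(
    f_xyz = f_xyz, f_xy = f_xy, f_yz = f_yz, f_xnz = f_xnz,
    f_x = f_x, f_y = f_y, f_z = f_z
  ))
  denom <- f_xy * f_yz * f_xnz
  if (denom == 0) return(0)
  (f_xyz * f_x * f_y * f_z) / denom
}

check_freq <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf(
      "frequencies must lie in [0, 1]; offending: %s",
      paste(names(x)[!is.finite(x) | x < 0 | x > 1], collapse = ", ")
    )
  }
  invisible(x)
}

#' Extract the 101-element composition feature vector of a sequence
#'
#' Counts overlapping k-mers (k = 1, 2, 3) on the given strand only, after
#' uppercasing and mapping U to T, and assembles the feature vector defined
#' by [feature_schema()]. Windows containing any ambiguous base (IUPAC codes
#' other than A/C/G/T) are skipped and excluded from both numerators and
#' denominators, so each absolute-frequency block sums to 1 over the counted
#' windows. The nucleic-acid type is appended as +1 (DNA) / -1 (RNA); it is
#' required metadata and never inferred from the residues.
#'
#' @param residues Sequence string (DNA or RNA alphabet, IUPAC ambiguity
#'   codes allowed, case-insensitive).
#' @param nucleic_acid `"DNA"` or `"RNA"` (case-insensitive).
#' @return Named numeric vector of length 101 aligned to [feature_schema()].
#' @examples
#' v <- extract_features("ACGACG", "RNA")
#' v[["rho_AC"]] # 3.6
#' @export
extract_features <- function(residues, nucleic_acid) {
  if (length(nucleic_acid) != 1L || is.na(nucleic_acid) ||
      !toupper(nucleic_acid) %in% c("DNA", "RNA")) {
    stopf("nucleic_acid must be \"DNA\" or \"RNA\"")
  }
  seq <- normalize_residues(residues)
  if (nchar(seq) < 3L) {
    stopf("sequence too short: need at least 3 bases, got %d", nchar(seq))
  }
  x <- Biostrings::DNAString(seq)
  # oligonucleotideFrequency() counts only windows made of A/C/G/T, so
  # ambiguity codes drop out of numerator and denominator alike.
  c1 <- Biostrings::oligonucleotideFrequency(x, 1)
  c2 <- Biostrings::oligonucleotideFrequency(x, 2)
  c3 <- Biostrings::oligonucleotideFrequency(x, 3)
  n1 <- sum(c1); n2 <- sum(c2); n3 <- sum(c3)
  if (n3 < 1L) {
    stopf("sequence has no unambiguous trinucleotide window")
  }
  f1 <- c1 / n1
  f2 <- c2 / n2
  f3 <- c3 / n3

  di <- names(f2)
  tri <- names(f3)
  # gapped frequency f_XNZ: sum f3 over the middle base
  first <- substr(tri, 1, 1)
  third <- substr(tri, 3, 3)
  fxnz_tab <- tapply(f3, list(first, third), sum)

  rho <- vapply(di, function(w) {
    a <- substr(w, 1, 1); b <- substr(w, 2, 2)
    relative_dinucleotide_frequency(f2[[w]], f1[[a]], f1[[b]])
  }, numeric(1))

  gamma <- vapply(tri, function(w) {
    a <- substr(w, 1, 1); b <- substr(w, 2, 2); d <- substr(w, 3, 3)
    relative_trinucleotide_frequency(
      f3[[w]],
      f2[[paste0(a, b)]], f2[[paste0(b, d)]], fxnz_tab[a, d],
      f1[[a]], f1[[b]], f1[[d]]
    )
  }, numeric(1))

  out <- c(
    f1, f2, rho, gamma,
    if (toupper(nucleic_acid) == "DNA") 1 else -1
  )
  names(out) <- feature_schema()
  out
}

#' Extract the feature matrix of a corpus
#'
#' Applies [extract_features()] to every record of a corpus table.
#'
#' @param corpus Data frame with columns `id`, `residues` and `nucleic_acid`
#'   (additional columns such as `host_lineage` are ignored here), e.g. from
#'   [generate_corpus()] or [read_corpus()].
#' @return Numeric matrix, one row per record (rownames = record ids), 101
#'   columns named after [feature_schema()].
#' @export
extract_feature_matrix <- function(corpus) {
  need <- c("id", "residues", "nucleic_acid")
  if (!is.data.frame(corpus) || !all(need %in% names(corpus))) {
    stopf("corpus must be a data frame with columns %s",
          paste(need, collapse = ", "))
  }
  X <- t(vapply(
    seq_len(nrow(corpus)),
    function(i) extract_features(corpus$residues[i], corpus$nucleic_acid[i]),
    numeric(101L)
  ))
  rownames(X) <- corpus$id
  X
}

#' Fit per-feature standardization parameters
#'
#' Estimates the per-feature mean and (population) standard deviation on a
#' training feature matrix so that features can be mapped to zero mean and
#' unit variance. Parameters must be fitted on training data only and then
#' applied unchanged to held-out data.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @return Object of class `vh_standardization` with elements `mean` and
#'   `sd` (both named by column).
#' @seealso [standardize()]
#' @export
fit_standardization <- function(X) {
  X <- as.matrix(X)
  structure(
    list(
      mean = colMeans(X),
      sd = apply(X, 2L, sd_pop)
    ),
    class = "vh_standardization"
  )
}

#' Apply standardization parameters to a feature matrix
#'
#' Computes `z = (x - mean) / sd` per feature. Degenerate features whose
#' fitted standard deviation is 0 are mapped to 0.
#'
#' @param X Numeric feature matrix or a single feature vector.
#' @param params A `vh_standardization` object from [fit_standardization()].
#' @return Standardized matrix (or vector) with the same shape as `X`.
#' @export
standardize <- function(X, params) {
  if (!inherits(params, "vh_standardization")) {
    stopf("params must come from fit_standardization()")
  }
  vec <- is.null(dim(X))
  X <- if (vec) matrix(X, nrow = 1L, dimnames = list(NULL, names(X))) else as.matrix(X)
  if (ncol(X) != length(params$mean)) {
    stopf("feature count mismatch: matrix has %d columns, params %d",
          ncol(X), length(params$mean))
  }
  if (!is.null(colnames(X)) && !is.null(names(params$mean)) &&
      !identical(colnames(X), names(params$mean))) {
    stopf("feature names do not match the standardization parameters")
  }
  Z <- sweep(X, 2L, params$mean, "-")
  sdv <- params$sd
  pos <- sdv > 0
  Z[, pos] <- sweep(Z[, pos, drop = FALSE], 2L, sdv[pos], "/")
  Z[, !pos] <- 0
  if (vec) Z[1L, ] else Z
}
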