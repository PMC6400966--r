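Package: viralhost
Title: Host Taxon Prediction for Viral Genomic Sequences from Nucleotide
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free prediction of the host superkingdom of a virus
    (phage versus eukaryote-infecting) from the nucleotide composition of its
    genome. Sequences are transformed into 101-element feature vectors
    (mononucleotide and dinucleotide frequencies, relative dinucleotide and
    trinucleotide frequencies computed on a single strand, and the nucleic
    acid type), and binary classifiers (logistic regression, k-nearest
    neighbours, quadratic discriminant analysis, and linear-kernel support
    vector classification) are trained and selected with a cross-validated
    fitness criterion combining mean and dispersion of the Matthews
    correlation coefficient and the area under the ROC curve. The package
    also provides wrapper feature-subset searches (an iterative bottom-up
    algorithm and a genetic algorithm), embedded and filter selectors (lasso
    path, recursive feature elimination, ANOVA-F ranking), lineage-aware
    data partitioning with exponential per-lineage sampling, a metagenomic
    fragment simulator, a feature-subset intersection randomization test,
    and a seeded synthetic-corpus generator so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
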