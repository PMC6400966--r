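test_that("lineage roots map to classes and host groups", {
  lab <- label_from_lineage(c(
    "Bacteria; Proteobacteria; Gammaproteobacteria",
    "Archaea; Euryarchaeota",
    "Eukaryota; Metazoa; Chordata; Craniata; Vertebrata; Mammalia",
    "Eukaryota; Viridiplantae; Streptophyta; Spermatophyta",
    "Eukaryota; Metazoa; Ecdysozoa; Arthropoda; Insecta",
    "Eukaryota; Fungi; Dikarya"
  ))
  expect_identical(lab$class, c(
    "phage", "phage", rep("eukaryote-infecting", 4)
  ))
  expect_identical(lab$group, c(
    NA, NA, "vertebrate", "seed-plant", "arthropod", "other"
  ))
  expect_error(label_from_lineage(""), "unrecognized")
  expect_error(label_from_lineage("Viruses; something"), "unrecognized")
})

test_that("per-lineage sampling probability follows the exponential decay", {
  expect_equal(sampling_probability(1, 0.217), exp(-1))
  expect_equal(sampling_probability(1, 1.5), exp(-1)) # 1^alpha = 1 for any alpha
  expect_equal(sampling_probability(2, 0.217), exp(-2^0.217))
  p <- sampling_probability(1:50, 0.217)
  expect_true(all(diff(p) < 0)) # strictly decreasing in rank
  expect_error(sampling_probability(0), "positive")
  expect_error(sampling_probability(2, -1), "positive")
})

test_that("alpha calibration reproduces expected counts and recovers itself", {
  # two lineages of sizes 3 and 2 at the canonical exponent
  expected <- sum(exp(-(1:3)^0.217)) + sum(exp(-(1:2)^0.217))
  expect_equal(expected, 1.642334, tolerance = 1e-6)
  # self-consistency: target the expected count, recover the exponent
  alpha_hat <- optimize_alpha(c(3, 2), expected)
  expect_equal(alpha_hat, 0.217, tolerance = 1e-3)
  # larger problem
  sizes <- c(40, 25, 10, 8, 5, 3, 1, 1)
  target <- sum(vapply(sizes, function(s) sum(sampling_probability(seq_len(s), 0.7)),
                       numeric(1)))
  expect_equal(optimize_alpha(sizes, target), 0.7, tolerance = 1e-3)
  # unreachable target returns the boundary with a warning
  expect_warning(a <- optimize_alpha(c(2, 2), 100), "boundary")
  expect_equal(a, 0.01)
})

test_that("partition separates test from cross-validation and balances folds", {
  corpus <- separated_corpus()$corpus
  part <- partition_viruses(corpus, seed = 12)
  expect_s3_class(part, "vh_partition")
  expect_setequal(part$id, corpus$id)
  cv <- part$id[grepl("^cv", part$split)]
  test <- part$id[part$split == "test"]
  expect_length(intersect(cv, test), 0L)
  # folds partition the cv set with near-equal sizes within each class
  for (cl in unique(part$class)) {
    tab <- table(part$split[part$class == cl & grepl("^cv", part$split)])
    expect_lte(max(tab) - min(tab), 1L)
  }
  # fold lookup round-trips
  folds <- partition_folds(part, cv)
  expect_true(all(folds %in% 1:5))
  expect_error(partition_folds(part, test), "cross-validation")
})

test_that("partition is deterministic and invariant to input order", {
  corpus <- separated_corpus()$corpus
  p1 <- partition_viruses(corpus, seed = 12)
  p2 <- partition_viruses(corpus, seed = 12)
  expect_identical(p1, p2)
  perm <- withr::with_seed(5, sample(nrow(corpus)))
  p3 <- partition_viruses(corpus[perm, ], seed = 12)
  o1 <- p1[order(p1$id), ]
  o3 <- p3[order(p3$id), ]
  rownames(o1) <- rownames(o3) <- NULL
  expect_identical(o1, o3)
})

test_that("exponential thinning balances a 1:4 imbalanced corpus", {
  # metadata-only table: partitioning never looks at the residues
  withr::with_seed(31, {
    n_phage <- 600L
    n_euk <- 2400L
    phage_lin <- sprintf("Bacteria; Phylum_%02d; Family_%02d",
                         sample(1:12, n_phage, TRUE), sample(1:12, n_phage, TRUE))
    euk_lin <- sprintf("Eukaryota; Clade_%02d; Vertebrata; Species_%02d",
                       sample(1:15, n_euk, TRUE), sample(1:15, n_euk, TRUE))
  })
  viruses <- data.frame(
    id = sprintf("V%04d", seq_len(n_phage + n_euk)),
    host_lineage = c(phage_lin, euk_lin),
    stringsAsFactors = FALSE
  )
  # calibrate alpha so the expected euk cv count matches the phage cv count
  probe <- partition_viruses(viruses, alpha = 0.5, seed = 77)
  n_phage_cv <- sum(probe$class == "phage" & grepl("^cv", probe$split))
  euk_cand <- probe$split[probe$class == "eukaryote-infecting"] != "test"
  cand_lineages <- viruses$host_lineage[probe$class == "eukaryote-infecting"][euk_cand]
  # candidate ids are the same for any alpha (test lineages are alpha-free)
  sizes <- as.integer(table(cand_lineages))
  alpha <- optimize_alpha(sizes, n_phage_cv)
  part <- partition_viruses(viruses, alpha = alpha, seed = 77)
  counts <- table(part$class[grepl("^cv", part$split)])
  expect_lt(
    abs(diff(counts)) / max(counts), 0.10
  )
})

test_that("genome-type strata appear in both cross-validation and test sets", {
  withr::with_seed(13, {
    n <- 400L
    viruses <- data.frame(
      id = sprintf("V%03d", seq_len(n)),
      host_lineage = c(
        sprintf("Bacteria; Phylum_%02d; Family_%02d",
                sample(1:10, n / 2, TRUE), sample(1:10, n / 2, TRUE)),
        sprintf("Eukaryota; Clade_%02d; Vertebrata",
                sample(1:10, n / 2, TRUE))
      ),
      genome_type = sample(c("dsDNA", "ssRNA+", "ssRNA-"), n, TRUE),
      stringsAsFactors = FALSE
    )
  })
  part <- partition_viruses(viruses, seed = 3)
  split_of <- setNames(part$split, part$id)
  gt <- setNames(viruses$genome_type, viruses$id)
  in_cv <- grepl("^cv", split_of)
  in_test <- split_of == "test"
  expect_setequal(unique(gt[names(split_of)[in_cv]]), unique(gt))
  expect_setequal(unique(gt[names(split_of)[in_test]]), unique(gt))
})

test_that("partition requires both classes and enough members", {
  one_class <- data.frame(
    id = sprintf("P%02d", 1:20),
    host_lineage = rep("Bacteria; X; Y", 20)
  )
  expect_error(partition_viruses(one_class), "both classes")
  tiny <- data.frame(
    id = c("P1", "P2", "E1", "E2"),
    host_lineage = c(rep("Bacteria; X", 2), rep("Eukaryota; Y", 2))
  )
  expect_error(partition_viruses(tiny, seed = 1), "at least")
})

test_that("partition tables round-trip through TSV", {
  corpus <- separated_corpus()$corpus
  part <- partition_viruses(corpus, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(back$id, part$id)
  expect_equal(back$split, part$split)
})
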