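test_that("allele names parse into locus, fields and suffix", {
  n <- parse_allele_name("B*53:06")
  expect_equal(n$locus, "B")
  expect_equal(n$fields, c(53L, 6L))
  expect_equal(n$suffix, "")

  n <- parse_allele_name("HLA-DQA1*01:02:01:04")
  expect_equal(n$locus, "DQA1")
  expect_equal(n$fields, c(1L, 2L, 1L, 4L))
  expect_equal(format(n), "DQA1*01:02:01:04")

  n <- parse_allele_name("C*04:09N")
  expect_equal(n$suffix, "N")
  expect_equal(format(n), "C*04:09N")
})

test_that("malformed allele names are rejected with the offending token", {
  expect_error(parse_allele_name("B53:06"), "\\*")
  expect_error(parse_allele_name("B*53:0x6"), "0x6")
  expect_error(parse_allele_name("*53:06"), "malformed")
  expect_error(parse_allele_name("B*01:02:03:04:05"), "1-4")
})

test_that("parse -> render -> parse is the identity on generated names", {
  set.seed(42)
  loci <- c("A", "B", "C", "DQA1", "DQB1", "DPA1", "DRB1")
  for (i in 1:200) {
    k <- sample(1:4, 1L)
    fields <- sprintf("%02d", sample(0:399, k, replace = TRUE))
    suffix <- sample(c("", "N", "Q", "L"), 1L)
    text <- paste0(sample(loci, 1L), "*", paste(fields, collapse = ":"), suffix)
    expect_identical(format(parse_allele_name(text)), text)
  }
})

test_that("allele groups follow locus and first field", {
  expect_equal(allele_group("B*53:06"), allele_group("B*53:01:01:01"))
  expect_false(allele_group("B*53:06") == allele_group("B*51:01:01:04"))
  expect_equal(allele_group("B*53:06"), allele_group("B*53:06"))
  # same first field at another locus is a different group
  expect_false(allele_group("A*53:06") == allele_group("B*53:06"))
})

test_that("ordering is lexicographic on integer fields, a strict total order", {
  expect_equal(sort_allele_names(c("A*03:13", "A*03:01:01:01")),
               c("A*03:01:01:01", "A*03:13"))
  # prefix precedes extension; suffix ignored
  expect_equal(sort_allele_names(c("B*27:05:02", "B*27:05")),
               c("B*27:05", "B*27:05:02"))
  expect_equal(compare_allele_names("A*03:13", "A*03:13"), 0L)
  set.seed(7)
  names <- replicate(30, paste0("B*", paste(
    sprintf("%02d", sample(0:120, sample(1:4, 1L), replace = TRUE)),
    collapse = ":")))
  keys <- allele_name_key(names)
  ord <- order(keys, names)
  sorted <- names[ord]
  for (i in seq_len(length(sorted) - 1L)) {
    expect_lte(compare_allele_names(sorted[i], sorted[i + 1L]), 0L)
  }
})

test_that("gene models validate structure and lengths", {
  expect_error(gene_model("X", c("E1", "UTR3"), c(3, 1)), "UTR5")
  expect_error(gene_model("X", c("UTR5", "E1", "E2", "UTR3"), c(0, 3, 3, 0)),
               "alternate")
  expect_error(gene_model("X", c("UTR5", "E1", "I1", "UTR3"), c(0, 3, 4, 0)),
               "alternate")
  expect_error(gene_model("X", c("UTR5", "E1", "UTR3"), c(0, 0, 0)), ">= 1")
  m <- gene_model("X", c("UTR5", "E1", "I1", "E2", "UTR3"), c(0, 3, 4, 5, 0))
  expect_equal(model_cds_length(m), 8L)
})

test_that("genomic positions map to features per the coordinate convention", {
  m <- gene_model("TOY", c("UTR5", "E1", "I1", "E2", "UTR3"), c(2, 3, 4, 5, 2))
  expect_equal(genomic_to_feature(m, -1), list(feature = "UTR5", offset = 2L))
  expect_equal(genomic_to_feature(m, 1), list(feature = "E1", offset = 1L))
  # toy model E1=3, I1=4, E2=5: position 8 is the first base of E2
  expect_equal(genomic_to_feature(m, 8), list(feature = "E2", offset = 1L))
  expect_error(genomic_to_feature(m, 0), "0")
  expect_error(genomic_to_feature(m, 15), "outside")
})

test_that("genomic_to_feature and feature_to_genomic compose to identity", {
  set.seed(11)
  for (rep in 1:20) {
    n_ex <- sample(2:5, 1L)
    feats <- c("UTR5", as.vector(rbind(paste0("E", 1:n_ex),
                                       c(paste0("I", seq_len(n_ex - 1L)), NA))))
    feats <- c(feats[!is.na(feats)], "UTR3")
    lens <- c(sample(0:30, 1L), sample(1:40, 2L * n_ex - 1L, replace = TRUE),
              sample(0:30, 1L))
    m <- gene_model("R", feats, lens)
    span <- model_span(m)
    positions <- setdiff(seq(span[1L], span[2L]), 0L)
    for (pos in sample(positions, min(25L, length(positions)))) {
      f <- genomic_to_feature(m, pos)
      expect_equal(feature_to_genomic(m, f$feature, f$offset), pos)
    }
  }
})

test_that("canonical models carry the published coding arithmetic", {
  models <- hla_gene_models()
  expect_equal(model_cds_length(models[["A"]]), 1098L)
  expect_equal(model_cds_length(models[["B"]]), 1089L)
  expect_equal(model_cds_length(models[["C"]]), 1101L)
  expect_true(all(vapply(models, function(m) model_cds_length(m) %% 3L == 0L,
                         logical(1L))))
  # coordinate anchors: known difference positions fall in the right features
  expect_equal(genomic_to_feature(models[["A"]], 2605)$feature, "I6")
  expect_equal(genomic_to_feature(models[["B"]], 1127)$feature, "I3")
  expect_equal(genomic_to_feature(models[["B"]], 2180)$feature, "I5")
  expect_equal(genomic_to_feature(models[["B"]], 3014)$feature, "UTR3")
  expect_equal(genomic_to_feature(models[["C"]], 993)$feature, "E3")
  expect_equal(genomic_to_feature(models[["C"]], 1030)$feature, "I3")
  expect_equal(genomic_to_feature(models[["C"]], -415)$feature, "UTR5")
  expect_equal(genomic_to_feature(models[["DQA1"]], 3974)$feature, "E2")
  expect_equal(genomic_to_feature(models[["DQA1"]], 3105)$feature, "I1")
  expect_equal(genomic_to_feature(models[["DQB1"]], 744)$feature, "I1")
  expect_equal(genomic_to_feature(models[["DQB1"]], 3363)$feature, "I2")
})

test_that("allele records validate sequence length and feature subsets", {
  m <- toy_model()
  full <- allele_record("SYN*01:01", random_seq(model_span_length(m)), m)
  expect_equal(full$coverage_end, model_span(m)[2L])
  expect_error(allele_record("SYN*01:02", "ACGT", m), "length")
  expect_error(allele_record("SYN*01:03", "ACGT", m, known_features = "E9"),
               "E9")
  partial <- degrade_to_partial(full, c("E2", "E3"), m)
  expect_equal(partial$known_features, c("E2", "E3"))
  expect_equal(nchar(partial$sequence), 270L + 120L)
  expect_equal(record_feature_sequence(partial, m, "E2"),
               record_feature_sequence(full, m, "E2"))
})
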