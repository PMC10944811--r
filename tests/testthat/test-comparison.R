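test_that("reference selection follows group order, coverage and fallbacks", {
  models <- hla_gene_models()
  a <- models[["A"]]
  b <- models[["B"]]
  full_a <- function(name) allele_record(name, random_seq(model_span_length(a)), a)
  full_b <- function(name) allele_record(name, random_seq(model_span_length(b)), b)
  trunc_b <- function(name, cov) {
    span <- model_span(b)
    len <- model_span_length(b) - (span[2L] - cov)
    allele_record(name, random_seq(len), b, coverage_end = cov)
  }
  set.seed(1)

  db <- allele_db(list(full_a("A*03:01:01:01"), full_a("A*03:99")),
                  models["A"])
  sel <- select_reference("A*03:13", db)
  expect_equal(sel$reference, "A*03:01:01:01")
  expect_false(sel$fallback)

  # the group's first allele is only known to 2707; the span to 3799 forces a
  # fallback to the lowest group member covering it
  db <- allele_db(list(trunc_b("B*27:01", 2707L), full_b("B*27:04:01"),
                       full_b("B*27:05:02:01")), models["B"])
  sel <- select_reference("B*27:23", db, required_span = c(-285L, 3799L))
  expect_equal(sel$reference, "B*27:04:01")
  expect_true(sel$fallback)
  expect_false(sel$cross_group)
  # without a coverage requirement the first allele is kept
  sel2 <- select_reference("B*27:23", db, required_span = c(-285L, 2700L))
  expect_equal(sel2$reference, "B*27:01")
  expect_false(sel2$fallback)

  # no group member at all: configured cross-group reference, flagged
  db <- allele_db(list(full_b("B*42:01:01:01"), full_b("B*07:02:01:01")),
                  models["B"])
  sel <- select_reference("B*41:02:01:05", db, required_span = c(1L, 3698L),
                          cross_group_reference = "B*42:01:01:01")
  expect_equal(sel$reference, "B*42:01:01:01")
  expect_true(sel$fallback)
  expect_true(sel$cross_group)
  expect_error(select_reference("B*41:02:01:05",
                                allele_db(list(full_b("B*07:02:01:01")),
                                          models["B"]),
                                required_span = c(1L, 3698L)),
               "no candidate")
})

test_that("alignment scores match an exhaustive-search oracle", {
  aln <- align_pair("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(aln$query, aln$reference)
  expect_equal(aln$score, 10)

  aln <- align_pair("ACGT", "ACT")
  expect_equal(aln$score, oracle_align_score("ACGT", "ACT"))
  expect_equal(gsub("-", "", aln$query), "ACGT")
  expect_equal(gsub("-", "", aln$reference), "ACT")
  expect_equal(nchar(aln$query), nchar(aln$reference))

  set.seed(23)
  for (i in 1:40) {
    a <- random_seq(8)
    b <- random_seq(8)
    expect_equal(align_pair(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  expect_error(align_pair("ACGT", "AC!T"), "non-nucleotide")
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("difference catalogue renders the field notation per region", {
  models <- hla_gene_models()
  a <- models[["A"]]
  set.seed(9)
  ref <- random_seq(model_span_length(a))
  utr5 <- a$lengths[["UTR5"]]
  idx2605 <- 2605L + utr5
  ref <- substitute_at(ref, idx2605, "C")
  qry <- substitute_at(ref, idx2605, "T")
  diffs <- catalogue_differences(as_alignment(qry, ref), a)
  expect_equal(nrow(diffs), 1L)
  expect_equal(diffs$rendered, "I6 C2605T")
  expect_equal(diffs$region, "I6")

  c_model <- models[["C"]]
  ref <- random_seq(model_span_length(c_model))
  idx <- genomic_to_index_for_test(-415L, c_model)
  ref <- substitute_at(ref, idx, "G")
  qry <- substitute_at(ref, idx, "A")
  diffs <- catalogue_differences(as_alignment(qry, ref), c_model)
  expect_equal(diffs$rendered, "5'UTR G-415A")

  # single A inserted after DQA1 position 3205 (the homopolymer insertion)
  dqa1 <- models[["DQA1"]]
  ref <- random_seq(model_span_length(dqa1))
  idx <- genomic_to_index_for_test(3205L, dqa1)
  qry <- paste0(substring(ref, 1L, idx), "A", substring(ref, idx + 1L))
  diffs <- catalogue_differences(align_pair(qry, ref), dqa1)
  ins <- diffs[diffs$kind == "insertion", , drop = FALSE]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$alt, "A")
  # an equivalent placement within the same run is acceptable; the rendered
  # interval must sit in intron 1 next to 3205
  expect_match(ins$rendered, "^I1 3[0-9]{3}_3[0-9]{3}insA$")

  expect_equal(nrow(catalogue_differences(as_alignment(ref, ref), dqa1)), 0L)
})

test_that("catalogue symmetry, ambiguity exclusion and deletion merging", {
  m <- toy_model()
  set.seed(13)
  ref <- random_seq(model_span_length(m))
  qry <- flip_base(flip_base(ref, 150L), 600L)
  d1 <- catalogue_differences(as_alignment(qry, ref), m)
  d2 <- catalogue_differences(as_alignment(ref, qry), m)
  expect_equal(d1$position, d2$position)
  expect_equal(d1$ref, d2$alt)
  expect_equal(d1$alt, d2$ref)

  # N in the query is a superset of any base: excluded, not a difference
  qry_n <- substitute_at(ref, 200L, "N")
  expect_equal(nrow(catalogue_differences(as_alignment(qry_n, ref), m)), 0L)
  # R (A/G) against C overlaps nowhere: reported
  ref_c <- substitute_at(ref, 200L, "C")
  qry_r <- substitute_at(ref_c, 200L, "R")
  expect_equal(nrow(catalogue_differences(as_alignment(qry_r, ref_c), m)), 1L)

  # a 3-base deletion merges into one rendered event
  qry_del <- paste0(substring(ref, 1L, 400L), substring(ref, 404L))
  diffs <- catalogue_differences(align_pair(qry_del, ref), m)
  del <- diffs[diffs$kind == "deletion", , drop = FALSE]
  expect_equal(nrow(del), 1L)
  expect_equal(nchar(del$ref), 3L)
  expect_match(del$rendered, "del")
})

test_that("addition accounting reproduces the published exon arithmetic", {
  models <- hla_gene_models()
  a <- models[["A"]]
  full <- allele_record("A*03:13", strrep("A", model_span_length(a)), a)
  acc <- count_added_nucleotides(c("E2", "E3"), full, a)
  expect_equal(acc$coding_added, 552L)
  expect_equal(acc$coding_added + acc$noncoding_added,
               model_span_length(a) - 270L - 276L)

  # all exons known: only non-coding can be added
  acc2 <- count_added_nucleotides(model_exons(a), full, a)
  expect_equal(acc2$coding_added, 0L)
  expect_gt(acc2$noncoding_added, 0L)

  # everything known already: zero account, not an error
  acc3 <- count_added_nucleotides(a$features, full, a)
  expect_equal(acc3$coding_added, 0L)
  expect_equal(acc3$noncoding_added, 0L)

  # partial 3'UTR extension beyond the previous coverage end
  b <- models[["B"]]
  full_b <- allele_record("B*27:23", strrep("A", model_span_length(b)), b)
  acc4 <- count_added_nucleotides(b$features, full_b, b,
                                  prev_coverage_end = 2707L)
  expect_equal(acc4$coding_added, 0L)
  expect_equal(acc4$noncoding_added, 3799L - 2707L)

  expect_error(count_added_nucleotides(c("E2", "E9"), full, a), "subset")
})

test_that("addition accounts conserve the newly resolved territory", {
  set.seed(31)
  for (rep in 1:20) {
    m <- toy_model()
    feats <- m$features
    new_known <- sort(sample(seq_along(feats),
                             sample(2:length(feats), 1L)))
    prev_known <- new_known[sample(c(TRUE, FALSE), length(new_known),
                                   replace = TRUE)]
    rec_feats <- feats[new_known]
    ft <- model_feature_table(m)
    len <- sum(ft$length[match(rec_feats, ft$feature)])
    rec <- allele_record("SYN*01:01", strrep("A", len), m,
                         known_features = rec_feats)
    acc <- count_added_nucleotides(feats[prev_known], rec, m)
    newly <- setdiff(rec_feats, feats[prev_known])
    expect_equal(acc$coding_added + acc$noncoding_added,
                 sum(ft$length[match(newly, ft$feature)]))
  }
})
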