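#' Translate exon 2 of an allele with mature-protein numbering
#'
#' Translates the exon-2 sequence of a record with the standard genetic code
#' and maps each residue to mature-protein numbering. The reading frame is
#' derived from the coding length of the preceding exons (a split codon at
#' the exon boundary is skipped); the mature number of a residue is its
#' precursor codon index minus the locus signal-peptide length from the gene
#' model.
#'
#' @param record An `hla_allele_record` whose `E2` is resolved.
#' @param model The locus `hla_gene_model` (with `signal_peptide_len` set for
#'   mature numbering; 0 when the translation starts at the mature
#'   N-terminus).
#' @return An object of class `hla_exon_translation`: `protein` (string,
#'   `*` for stops), `mature_positions` (integer vector, one per residue),
#'   `has_premature_stop`.
#' @examples
#' # GAA at the codon mapped to mature residue 45 translates to E45
#' @export
translate_exon2 <- function(record, model) {
  if (!"E2" %in% record$known_features) {
    stop("exon 2 is not resolved in ", format(record$name))
  }
  e2 <- record_feature_sequence(record, model, "E2")
  exons <- model_exons(model)
  before <- exons[seq_len(match("E2", exons) - 1L)]
  prev_cds <- sum(model$lengths[before])
  phase <- prev_cds %% 3L
  lead_trim <- if (phase == 0L) 0L else 3L - phase
  first_codon <- if (phase == 0L) prev_cds %/% 3L + 1L else prev_cds %/% 3L + 2L
  coding <- substring(e2, lead_trim + 1L)
  n_codons <- nchar(coding) %/% 3L
  if (n_codons < 1L) stop("exon 2 too short to translate in frame")
  coding <- substring(coding, 1L, n_codons * 3L)
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(coding), if.fuzzy.codon = "X"
  ))
  spl <- model$signal_peptide_len
  if (is.na(spl)) spl <- 0L
  mature <- first_codon + seq_len(n_codons) - 1L - spl
  aa <- strsplit(protein, "")[[1L]]
  structure(
    list(protein = protein, mature_positions = mature,
         has_premature_stop = any(aa == "*")),
    class = "hla_exon_translation"
  )
}

#' @export
print.hla_exon_translation <- function(x, ...) {
  cat("<hla_exon_translation> ", x$protein, "\n  mature positions ",
      x$mature_positions[1L], "..",
      x$mature_positions[length(x$mature_positions)], "\n", sep = "")
  invisible(x)
}

#' Residue at a mature-protein position
#' @param translation An `hla_exon_translation`.
#' @param position Mature-protein residue number.
#' @return Single amino-acid letter (NA when outside the translation).
#' @export
residue_at <- function(translation, position) {
  i <- match(position, translation$mature_positions)
  if (is.na(i)) return(NA_character_)
  substring(translation$protein, i, i)
}

#' Serotype classification rule
#'
#' A rule maps motifs over critical mature-protein residue positions to
#' serotypes; residues outside the table are unassigned. Optional
#' verification positions are residues expected to be invariant across the
#' serotypes the rule distinguishes.
#'
#' @param positions Integer vector of critical residue positions.
#' @param table Named character vector, motif (pasted residues) -> serotype.
#' @param verify_positions Optional invariant positions.
#' @return An object of class `hla_serotype_rule`.
#' @export
serotype_rule <- function(positions, table, verify_positions = integer(0L)) {
  stopifnot(is.numeric(positions), length(positions) >= 1L,
            is.character(table), !is.null(names(table)))
  if (any(nchar(names(table)) != length(positions))) {
    stop("every motif must have one residue per rule position")
  }
  structure(list(positions = as.integer(positions), table = table,
                 verify_positions = as.integer(verify_positions)),
            class = "hla_serotype_rule")
}

#' The DQ7/DQ8/DQ9 serotype rule
#'
#' The DQ7, DQ8 and DQ9 serotypes of DQB1*03 alleles are determined by the
#' mature beta-chain residues 45 and 57: ED or EA encodes DQ7, GA encodes
#' DQ8 and GD DQ9. Residues 74, 84 and 85 are invariant across the three
#' serotypes (verification positions). The rule ships as a config table.
#'
#' @return An `hla_serotype_rule`.
#' @examples
#' classify_serotype("E", "D", dq_serotype_rule())  # "DQ7"
#' @export
dq_serotype_rule <- function() {
  path <- system.file("extdata", "serotype_dq.tsv", package = "hlafull",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  serotype_rule(c(45L, 57L), stats::setNames(tab$serotype, tab$motif),
                verify_positions = c(74L, 84L, 85L))
}

#' Classify a serotype from critical residues
#'
#' Pure table lookup on the residues at the rule's critical positions.
#'
#' @param res45,res57 Single amino-acid letters at the two critical positions
#'   (for a two-position rule; pass further residues via `...`).
#' @param rule An `hla_serotype_rule` (default: the DQ7/8/9 rule).
#' @param ... Additional residues for rules with more positions.
#' @return The serotype string, or `"unassigned"` when the motif is not in
#'   the table.
#' @examples
#' classify_serotype("G", "A")  # "DQ8"
#' classify_serotype("A", "A")  # "unassigned"
#' @export
classify_serotype <- function(res45, res57, rule = dq_serotype_rule(), ...) {
  motif <- paste0(res45, res57, ...)
  if (nchar(motif) != length(rule$positions)) {
    stop("expected ", length(rule$positions), " residues for this rule")
  }
  if (motif %in% names(rule$table)) unname(rule$table[[motif]]) else "unassigned"
}

#' Classify the serotype of an allele record
#'
#' Translates exon 2 and applies a serotype rule to the residues at its
#' critical positions.
#'
#' @param record An `hla_allele_record` with exon 2 resolved.
#' @param model The locus `hla_gene_model`.
#' @param rule An `hla_serotype_rule`.
#' @return A list with `serotype`, `residues` (named by position) and the
#'   residues at the rule's verification positions.
#' @export
classify_allele_serotype <- function(record, model, rule = dq_serotype_rule()) {
  tr <- translate_exon2(record, model)
  res <- vapply(rule$positions, function(p) residue_at(tr, p), character(1L))
  names(res) <- rule$positions
  if (anyNA(res)) stop("critical residues outside the exon-2 translation")
  verify <- vapply(rule$verify_positions, function(p) residue_at(tr, p),
                   character(1L))
  names(verify) <- rule$verify_positions
  list(serotype = do.call(classify_serotype,
                          c(as.list(unname(res)), list(rule = rule))),
       residues = res, verification = verify)
}

#' Find homopolymer tracts in a sequence
#'
#' Reports every maximal single-base run of at least `min_len` nucleotides.
#' Runs of 7-10 or more are prone to replication slippage and sequencing
#' error, hence the default threshold of 7.
#'
#' @param sequence Nucleotide string.
#' @param min_len Minimum tract length (default 7).
#' @param start_pos Genomic position of the first base (default 1); tract
#'   coordinates are reported on this scale (no position 0 when the start is
#'   negative).
#' @return A data frame with columns `start`, `base`, `length`.
#' @examples
#' find_homopolymers(paste0("CC", strrep("A", 13), "GG"), min_len = 7)
#' @export
find_homopolymers <- function(sequence, min_len = 7L, start_pos = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$lengths >= min_len & runs$values %in% c("A", "C", "G", "T")
  # map string offsets to genomic coordinates (skipping position 0)
  offset_to_pos <- function(i) {
    p <- start_pos + i - 1L
    if (start_pos < 0L) ifelse(p >= 0L, p + 1L, p) else p
  }
  data.frame(start = offset_to_pos(starts[keep]),
             base = runs$values[keep],
             length = runs$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Compare homopolymer lengths across alleles at one locus position
#'
#' Measures, for each record, the maximal run of the tract base containing a
#' given genomic position (e.g. the intron-1 A-homopolymer of DQA1 starting
#' at position 3105) and tabulates the lengths by allele group. Records in
#' which the position is not resolved are flagged, not fatal.
#'
#' @param records List of `hla_allele_record` objects at one locus.
#' @param model The locus `hla_gene_model`.
#' @param position Genomic position inside the tract.
#' @return A data frame with columns `allele`, `group`, `base`, `length`,
#'   `missing`.
#' @export
compare_homopolymer_lengths <- function(records, model, position) {
  feat <- genomic_to_feature(model, position)
  rows <- lapply(records, function(rec) {
    base_row <- data.frame(allele = format(rec$name),
                           group = allele_group(rec$name),
                           base = NA_character_, length = NA_integer_,
                           missing = TRUE, stringsAsFactors = FALSE)
    if (!feat$feature %in% rec$known_features) return(base_row)
    seq <- record_feature_sequence(rec, model, feat$feature)
    off <- feat$offset
    if (off > nchar(seq)) return(base_row)
    chars <- strsplit(seq, "")[[1L]]
    b <- chars[off]
    lo <- off
    while (lo > 1L && chars[lo - 1L] == b) lo <- lo - 1L
    hi <- off
    while (hi < length(chars) && chars[hi + 1L] == b) hi <- hi + 1L
    base_row$base <- b
    base_row$length <- hi - lo + 1L
    base_row$missing <- FALSE
    base_row
  })
  res <- do.call(rbind, rows)
  res[order(allele_name_key(res$allele)), , drop = FALSE]
}
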