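# IUPAC nucleotide code -> set of bases it denotes
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_nucleotide_string <- function(x) {
  !grepl("[^ACGTRYSWKMBDHVN]", toupper(x))
}

#' Globally align two allele sequences
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap costs. HLA
#' alleles of one locus are near-identical, so alignment is essentially
#' anchoring; defaults are match +1, mismatch -1, gap open -4, gap extend
#' -0.5 per base (a gap of length L costs 4 + 0.5 L).
#'
#' @param query,reference Nucleotide strings (IUPAC, case-insensitive).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties as
#'   positive magnitudes for the gap terms).
#' @return An object of class `hla_pairwise_alignment`: `query` and
#'   `reference` aligned strings of equal length (gap `-`), plus `score`.
#' @examples
#' align_pair("ACGT", "ACT")
#' @export
align_pair <- function(query, reference, match = 1, mismatch = -1,
                       gap_open = 4, gap_extend = 0.5) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  query <- toupper(query); reference <- toupper(reference)
  if (!nzchar(query) || !nzchar(reference)) {
    stop("cannot align empty sequences")
  }
  if (!is_nucleotide_string(query) || !is_nucleotide_string(reference)) {
    stop("sequences contain non-nucleotide characters")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aln <- structure(
    list(query = as.character(Biostrings::alignedPattern(pa)),
         reference = as.character(Biostrings::alignedSubject(pa)),
         score = BiocGenerics::score(pa)),
    class = "hla_pairwise_alignment"
  )
  aln
}

#' @export
print.hla_pairwise_alignment <- function(x, ...) {
  cat("<hla_pairwise_alignment> length ", nchar(x$query),
      ", score ", x$score, "\n", sep = "")
  invisible(x)
}

#' Build an alignment object from already-aligned strings
#'
#' For columnar inputs (e.g. synthetic no-indel families) no aligner run is
#' needed; this wraps two equal-length strings as an alignment.
#'
#' @param query,reference Equal-length aligned strings (gap `-` allowed).
#' @return An `hla_pairwise_alignment` (score NA).
#' @export
as_alignment <- function(query, reference) {
  query <- toupper(query); reference <- toupper(reference)
  if (nchar(query) != nchar(reference)) {
    stop("aligned strings must have equal length")
  }
  structure(list(query = query, reference = reference, score = NA_real_),
            class = "hla_pairwise_alignment")
}

region_label <- function(feature) {
  ifelse(feature == "UTR5", "5'UTR", ifelse(feature == "UTR3", "3'UTR", feature))
}

# TRUE when the column should be excluded from cataloguing: one IUPAC set
# contains the other (unknown/ambiguous stretches are non-comparable)
iupac_excluded <- function(a, b) {
  sa <- iupac_sets[[a]]; sb <- iupac_sets[[b]]
  all(sa %in% sb) || all(sb %in% sa)
}

#' Catalogue region-wise differences of an alignment
#'
#' Walks a pairwise alignment in reference coordinates and records every
#' substitution, insertion and deletion, labelled by the gene-model feature
#' (5'UTR, exon, intron, 3'UTR) containing the reference position and rendered
#' in the conventional notation (`I6 C2605T`, `5'UTR G-415A`,
#' `I1 3205_3206insA`, `E3 100_102delACG`). Adjacent inserted or deleted bases
#' are merged into single events. Columns where one IUPAC code is a subset of
#' the other (unknown or ambiguous sequence) are non-comparable and skipped;
#' region filtering (e.g. non-coding only) is left to the caller.
#'
#' @param aln An `hla_pairwise_alignment` whose `reference` string is the
#'   reference allele.
#' @param model The reference locus `hla_gene_model`.
#' @param ref_start Genomic position of the first reference base (defaults to
#'   the model start, i.e. a full-span reference).
#' @return A data frame of class `hla_region_differences` with columns
#'   `region`, `position`, `kind`, `ref`, `alt`, `rendered`.
#' @export
catalogue_differences <- function(aln, model, ref_start = NULL) {
  stopifnot(inherits(aln, "hla_pairwise_alignment"))
  q <- strsplit(aln$query, "")[[1L]]
  r <- strsplit(aln$reference, "")[[1L]]
  utr5 <- model$lengths[["UTR5"]]
  if (is.null(ref_start)) ref_start <- model_span(model)[1L]
  idx0 <- genomic_to_index(as.integer(ref_start), utr5) - 1L
  n_ref <- sum(r != "-")
  if (idx0 + n_ref > model_span_length(model)) {
    stop("reference model span shorter than the ungapped reference sequence")
  }

  out <- list()
  emit <- function(kind, idx_from, idx_to, ref, alt) {
    pos <- index_to_genomic(idx_from, utr5)
    feat <- genomic_to_feature(model, pos)$feature
    lab <- region_label(feat)
    rendered <- switch(
      kind,
      substitution = paste0(lab, " ", ref, pos, alt),
      insertion = {
        nxt <- index_to_genomic(idx_from + 1L, utr5)
        paste0(lab, " ", pos, "_", nxt, "ins", alt)
      },
      deletion = {
        if (idx_to > idx_from) {
          paste0(lab, " ", pos, "_", index_to_genomic(idx_to, utr5),
                 "del", ref)
        } else paste0(lab, " ", pos, "del", ref)
      }
    )
    out[[length(out) + 1L]] <<- data.frame(
      region = feat, position = pos, kind = kind, ref = ref, alt = alt,
      rendered = rendered, stringsAsFactors = FALSE
    )
  }

  idx <- idx0
  i <- 1L
  n <- length(r)
  while (i <= n) {
    if (r[i] == "-" && q[i] == "-") {
      i <- i + 1L
      next
    }
    if (r[i] == "-") {                       # insertion relative to reference
      j <- i
      while (j < n && r[j + 1L] == "-" && q[j + 1L] != "-") j <- j + 1L
      if (idx >= idx0 + 1L) {
        emit("insertion", idx, idx, "", paste(q[i:j], collapse = ""))
      }
      i <- j + 1L
      next
    }
    if (q[i] == "-") {                       # deletion relative to reference
      j <- i
      while (j < n && q[j + 1L] == "-" && r[j + 1L] != "-") j <- j + 1L
      emit("deletion", idx + 1L, idx + (j - i + 1L),
           paste(r[i:j], collapse = ""), "")
      idx <- idx + (j - i + 1L)
      i <- j + 1L
      next
    }
    idx <- idx + 1L
    if (q[i] != r[i] && !iupac_excluded(q[i], r[i])) {
      emit("substitution", idx, idx, r[i], q[i])
    }
    i <- i + 1L
  }

  if (length(out)) {
    res <- do.call(rbind, out)
  } else {
    res <- data.frame(region = character(), position = integer(),
                      kind = character(), ref = character(),
                      alt = character(), rendered = character(),
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("hla_region_differences", class(res))
  res
}
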