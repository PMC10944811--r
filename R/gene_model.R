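#' Construct a gene model
#'
#' A gene model is the ordered feature list of an HLA gene in IMGT-style
#' genomic coordinates: a 5'UTR, alternating exons (`E1..En`) and introns
#' (`I1..In-1`), and a 3'UTR, each with a length in nucleotides. Position 1 is
#' the first base of exon 1; 5'UTR positions are negative, counting back from
#' -1; there is no position 0.
#'
#' @param locus Locus label, e.g. `"A"` or `"DQB1"`.
#' @param features Character vector of feature ids in order
#'   (`UTR5`, `E1`, `I1`, ..., `UTR3`).
#' @param lengths Integer vector of feature lengths (nt). `UTR5`/`UTR3` may be
#'   0 (unknown); all other features must be at least 1.
#' @param signal_peptide_len Signal-peptide length in residues, used for
#'   mature-protein numbering of exon-2 translations (NA when not needed).
#' @return An object of class `hla_gene_model`.
#' @examples
#' toy_model <- gene_model("TOY", c("UTR5", "E1", "I1", "E2", "UTR3"),
#'                         c(0, 3, 4, 5, 0))
#' @export
gene_model <- function(locus, features, lengths, signal_peptide_len = NA_integer_) {
  stopifnot(is.character(locus), length(locus) == 1L,
            length(features) == length(lengths))
  lengths <- as.integer(lengths)
  if (features[1L] != "UTR5" || features[length(features)] != "UTR3") {
    stop("gene model must start with UTR5 and end with UTR3")
  }
  inner <- features[-c(1L, length(features))]
  ok_exon <- grepl("^E[0-9]+$", inner)
  ok_intron <- grepl("^I[0-9]+$", inner)
  if (!all(ok_exon | ok_intron)) {
    stop("unknown feature id(s): ",
         paste(inner[!(ok_exon | ok_intron)], collapse = ", "))
  }
  # exons and introns must alternate, starting and ending on an exon
  expected <- rep(c(TRUE, FALSE), length.out = length(inner))
  if (!length(inner) || !all(ok_exon == expected) || !ok_exon[length(inner)]) {
    stop("features must alternate exon/intron between UTR5 and UTR3")
  }
  utr <- features %in% c("UTR5", "UTR3")
  if (any(lengths[!utr] < 1L) || any(lengths[utr] < 0L)) {
    stop("feature lengths must be >= 1 (UTRs may be 0)")
  }
  m <- structure(
    list(locus = locus, features = features, lengths = stats::setNames(lengths, features),
         signal_peptide_len = as.integer(signal_peptide_len)),
    class = "hla_gene_model"
  )
  m
}

#' @export
print.hla_gene_model <- function(x, ...) {
  cat("<hla_gene_model> ", x$locus, ": ",
      paste0(x$features, "(", x$lengths, ")", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Feature table of a gene model
#'
#' @param model An `hla_gene_model`.
#' @return A data frame with columns `feature`, `length`, `start`, `end`
#'   (genomic coordinates) and `index_start`, `index_end` (1-based linear
#'   indices over the model span). Zero-length UTRs get NA coordinates.
#' @export
model_feature_table <- function(model) {
  len <- unname(model$lengths)
  ie <- cumsum(len)
  is <- ie - len + 1L
  utr5 <- model$lengths[["UTR5"]]
  start <- ifelse(len > 0L, index_to_genomic(is, utr5), NA_integer_)
  end <- ifelse(len > 0L, index_to_genomic(ie, utr5), NA_integer_)
  data.frame(feature = model$features, length = len,
             start = start, end = end,
             index_start = ifelse(len > 0L, is, NA_integer_),
             index_end = ifelse(len > 0L, ie, NA_integer_),
             stringsAsFactors = FALSE)
}

# linear index (1..span) <-> genomic coordinate (no zero; UTR5 negative)
index_to_genomic <- function(i, utr5_len) {
  ifelse(i > utr5_len, i - utr5_len, i - utr5_len - 1L)
}

genomic_to_index <- function(pos, utr5_len) {
  if (any(pos == 0L)) stop("genomic position 0 does not exist")
  ifelse(pos > 0L, pos + utr5_len, pos + utr5_len + 1L)
}

#' Total model span in nucleotides
#' @param model An `hla_gene_model`.
#' @return Integer span (sum of feature lengths).
#' @export
model_span_length <- function(model) sum(model$lengths)

#' Genomic coordinate range covered by a model
#' @param model An `hla_gene_model`.
#' @return Integer vector `c(start, end)` in genomic coordinates.
#' @export
model_span <- function(model) {
  utr5 <- model$lengths[["UTR5"]]
  c(index_to_genomic(1L, utr5), index_to_genomic(model_span_length(model), utr5))
}

#' Exon feature ids of a model
#' @param model An `hla_gene_model`.
#' @return Character vector of exon ids (`E1`, `E2`, ...).
#' @export
model_exons <- function(model) model$features[grepl("^E[0-9]+$", model$features)]

#' Coding-sequence length of a model
#' @param model An `hla_gene_model`.
#' @return Integer: sum of exon lengths.
#' @export
model_cds_length <- function(model) sum(model$lengths[model_exons(model)])

#' Map a genomic position to its feature
#'
#' Inverse of [feature_to_genomic()]: locates the feature containing a genomic
#' position and the 1-based offset within that feature. Negative positions map
#' into the 5'UTR.
#'
#' @param model An `hla_gene_model`.
#' @param pos Genomic position (non-zero integer within the model span).
#' @return A list with `feature` and `offset`.
#' @examples
#' m <- gene_model("TOY", c("UTR5", "E1", "I1", "E2", "UTR3"), c(2, 3, 4, 5, 2))
#' genomic_to_feature(m, 8)   # E2, offset 1
#' genomic_to_feature(m, -1)  # UTR5, offset 2 (last base)
#' @export
genomic_to_feature <- function(model, pos) {
  stopifnot(length(pos) == 1L)
  pos <- as.integer(pos)
  if (pos == 0L) stop("genomic position 0 does not exist")
  i <- genomic_to_index(pos, model$lengths[["UTR5"]])
  if (i < 1L || i > model_span_length(model)) {
    stop("position ", pos, " outside the span of the ", model$locus, " model")
  }
  ft <- model_feature_table(model)
  row <- which(!is.na(ft$index_start) & ft$index_start <= i & i <= ft$index_end)
  list(feature = ft$feature[row], offset = i - ft$index_start[row] + 1L)
}

#' Map a feature offset to its genomic position
#'
#' @param model An `hla_gene_model`.
#' @param feature Feature id.
#' @param offset 1-based offset within the feature (default 1 = first base).
#' @return Genomic position (integer).
#' @export
feature_to_genomic <- function(model, feature, offset = 1L) {
  ft <- model_feature_table(model)
  row <- match(feature, ft$feature)
  if (is.na(row)) stop("unknown feature ", sQuote(feature))
  offset <- as.integer(offset)
  if (offset < 1L || offset > ft$length[row]) {
    stop("offset ", offset, " outside feature ", feature)
  }
  index_to_genomic(ft$index_start[row] + offset - 1L, model$lengths[["UTR5"]])
}

#' Read gene models from a config file
#'
#' The config is tabular text with one feature per row: columns `locus`,
#' `feature`, `length`. An optional companion table supplies per-locus
#' signal-peptide lengths (columns `locus`, `signal_peptide_len`).
#'
#' @param path Path to the feature table.
#' @param signal_path Optional path to the signal-peptide table.
#' @return A named list of `hla_gene_model` objects, one per locus.
#' @export
read_gene_models <- function(path, signal_path = NULL) {
  if (!file.exists(path)) stop("gene model config not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("locus", "feature", "length") %in% names(tab))) {
    stop("gene model config must have columns locus, feature, length")
  }
  sp <- NULL
  if (!is.null(signal_path)) {
    sp <- utils::read.delim(signal_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  }
  loci <- unique(tab$locus)
  models <- lapply(loci, function(l) {
    sub <- tab[tab$locus == l, , drop = FALSE]
    spl <- NA_integer_
    if (!is.null(sp) && l %in% sp$locus) {
      spl <- sp$signal_peptide_len[match(l, sp$locus)]
    }
    gene_model(l, sub$feature, sub$length, signal_peptide_len = spl)
  })
  stats::setNames(models, loci)
}

#' Canonical HLA gene models shipped with the package
#'
#' Feature lengths for HLA-A, -B, -C, -DQA1, -DQB1 and -DPA1. Exon lengths
#' reproduce the coding-nucleotide arithmetic of IPD-IMGT/HLA submissions
#' (e.g. HLA-A coding exons 73/270/276/276/117/33/48/5 nt); intron and UTR
#' lengths are IMGT-scale values consistent with the genomic positions used in
#' difference reports.
#'
#' @return Named list of `hla_gene_model` objects.
#' @examples
#' models <- hla_gene_models()
#' model_cds_length(models[["A"]])  # 1098
#' @export
hla_gene_models <- function() {
  read_gene_models(
    system.file("extdata", "gene_models.tsv", package = "hlafull",
                mustWork = TRUE),
    system.file("extdata", "signal_peptides.tsv", package = "hlafull",
                mustWork = TRUE)
  )
}
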