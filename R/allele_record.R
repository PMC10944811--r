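#' Construct an allele record
#'
#' An allele record holds the resolved sequence of one allele: the allele
#' name, the set of gene-model features whose sequence is known, and the
#' nucleotide sequence itself (the concatenation, in model order, of the known
#' features). A partially resolved 3'UTR is expressed through `coverage_end`,
#' the highest genomic position known.
#'
#' @param name Allele name (string or `hla_allele_name`).
#' @param sequence Nucleotide string (IUPAC codes, case-insensitive).
#' @param model The locus `hla_gene_model`.
#' @param known_features Character vector of resolved feature ids; defaults to
#'   all features of the model.
#' @param coverage_end Highest known genomic position; defaults to the end of
#'   the last known feature. Only a truncated 3'UTR may shorten it.
#' @param validate Check the sequence length against the model (disable only
#'   for sequences carrying indels relative to the model).
#' @return An object of class `hla_allele_record`.
#' @export
allele_record <- function(name, sequence, model, known_features = model$features,
                          coverage_end = NULL, validate = TRUE) {
  name <- as_allele_name(name)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence)) {
    stop("sequence of ", format(name), " contains non-IUPAC characters")
  }
  unknown <- setdiff(known_features, model$features)
  if (length(unknown)) {
    stop("known_features not in the ", model$locus, " model: ",
         paste(unknown, collapse = ", "))
  }
  known_features <- model$features[model$features %in% known_features]
  ft <- model_feature_table(model)
  ft <- ft[ft$feature %in% known_features & ft$length > 0L, , drop = FALSE]
  if (!nrow(ft)) stop("record for ", format(name), " resolves no features")
  full_end <- ft$end[nrow(ft)]
  if (is.null(coverage_end)) coverage_end <- full_end
  coverage_end <- as.integer(coverage_end)
  expected_len <- sum(ft$length)
  if (coverage_end != full_end) {
    if (ft$feature[nrow(ft)] != "UTR3" || coverage_end < ft$start[nrow(ft)] - 1L ||
        coverage_end > full_end) {
      stop("coverage_end may only truncate the 3'UTR")
    }
    expected_len <- expected_len - (full_end - coverage_end)
  }
  if (validate && nchar(sequence) != expected_len) {
    stop("sequence length ", nchar(sequence), " of ", format(name),
         " does not match the ", expected_len,
         " nt implied by its known features")
  }
  structure(
    list(name = name, sequence = sequence, known_features = known_features,
         coverage_end = coverage_end, locus = model$locus),
    class = "hla_allele_record"
  )
}

#' @export
print.hla_allele_record <- function(x, ...) {
  cat("<hla_allele_record> ", format(x$name), ": ", nchar(x$sequence),
      " nt, features ", paste(x$known_features, collapse = ","),
      ", coverage to ", x$coverage_end, "\n", sep = "")
  invisible(x)
}

#' Genomic start position of a record
#'
#' @param record An `hla_allele_record`.
#' @param model The locus gene model.
#' @return Genomic position of the record's first base.
#' @export
record_start <- function(record, model) {
  ft <- model_feature_table(model)
  ft <- ft[ft$feature %in% record$known_features & ft$length > 0L, , drop = FALSE]
  ft$start[1L]
}

#' Extract the sequence of one feature from a record
#'
#' @param record An `hla_allele_record`.
#' @param model The locus gene model.
#' @param feature Feature id, which must be among the record's known features.
#' @return Nucleotide string of that feature (possibly truncated for a partial
#'   3'UTR).
#' @export
record_feature_sequence <- function(record, model, feature) {
  if (!feature %in% record$known_features) {
    stop("feature ", feature, " not resolved in ", format(record$name))
  }
  ft <- model_feature_table(model)
  ft <- ft[ft$feature %in% record$known_features & ft$length > 0L, , drop = FALSE]
  row <- match(feature, ft$feature)
  offset <- if (row > 1L) sum(ft$length[seq_len(row - 1L)]) else 0L
  len <- ft$length[row]
  if (feature == "UTR3" && record$coverage_end < ft$end[row]) {
    len <- len - (ft$end[row] - record$coverage_end)
  }
  substring(record$sequence, offset + 1L, offset + len)
}

#' Construct an allele database
#'
#' A database maps allele names to records and carries the per-locus gene
#' models; it stands in for a release of a curated allele repository.
#'
#' @param records List of `hla_allele_record` objects.
#' @param models Named list of `hla_gene_model` objects, keyed by locus.
#' @return An object of class `hla_allele_db`.
#' @export
allele_db <- function(records, models) {
  nms <- vapply(records, function(r) format(r$name), character(1L))
  if (anyDuplicated(nms)) {
    stop("duplicate allele names in database: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (r in records) {
    if (!r$locus %in% names(models)) {
      stop("no gene model for locus ", r$locus)
    }
  }
  structure(list(records = stats::setNames(records, nms), models = models),
            class = "hla_allele_db")
}

#' @export
print.hla_allele_db <- function(x, ...) {
  cat("<hla_allele_db> ", length(x$records), " records over loci ",
      paste(names(x$models), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Allele names present in a database
#' @param db An `hla_allele_db`.
#' @return Character vector of allele names in allele order.
#' @export
db_allele_names <- function(db) sort_allele_names(names(db$records))
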