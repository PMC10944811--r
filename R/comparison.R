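#' Select the comparison reference for a query allele
#'
#' The reference is the first (lowest-numbered) allele of the query's allele
#' group for which a genomic sequence is known. When that allele does not
#' cover the required span (e.g. its 3'UTR is truncated), the fallback order
#' is: the lowest-ordered group member that covers the span, then the group
#' member with the longest coverage, then a configured cross-group reference.
#' A reference other than the group's first allele is flagged `fallback`; a
#' reference from another allele group is additionally flagged `cross_group`.
#'
#' @param query Query allele name (string or `hla_allele_name`).
#' @param db An `hla_allele_db` of candidate reference records.
#' @param required_span Optional genomic interval `c(start, end)` the
#'   reference must cover.
#' @param cross_group_reference Allele name to fall back on when the query's
#'   group has no genomic record at all.
#' @return A list with `reference` (allele name string), `fallback`,
#'   `cross_group` (logicals) and `coverage_end` of the chosen record.
#' @examples
#' # A*03:13 against a db holding full-length A*03:01:01:01 selects the latter
#' @export
select_reference <- function(query, db, required_span = NULL,
                             cross_group_reference = NULL) {
  query <- as_allele_name(query)
  if (!length(db$records)) stop("allele database is empty")
  grp <- allele_group(query)
  qname <- format(query)
  members <- names(db$records)
  members <- members[members != qname &
                       vapply(members, function(m) allele_group(m) == grp,
                              logical(1L))]
  result <- function(ref, fallback, cross_group) {
    list(reference = ref, fallback = fallback, cross_group = cross_group,
         coverage_end = db$records[[ref]]$coverage_end)
  }
  if (!length(members)) {
    if (!is.null(cross_group_reference) &&
        format(as_allele_name(cross_group_reference)) %in% names(db$records)) {
      return(result(format(as_allele_name(cross_group_reference)),
                    fallback = TRUE, cross_group = TRUE))
    }
    stop("no candidate reference for ", qname,
         ": allele group ", grp, " has no genomic record",
         if (is.null(cross_group_reference)) " and no cross-group reference is configured")
  }
  members <- sort_allele_names(members)
  if (is.null(required_span)) {
    return(result(members[1L], fallback = FALSE, cross_group = FALSE))
  }
  model <- db$models[[query$locus]]
  covers <- vapply(members, function(m) {
    rec <- db$records[[m]]
    record_start(rec, model) <= required_span[1L] &&
      rec$coverage_end >= required_span[2L]
  }, logical(1L))
  if (covers[1L]) {
    return(result(members[1L], fallback = FALSE, cross_group = FALSE))
  }
  if (any(covers)) {
    return(result(members[which(covers)[1L]], fallback = TRUE,
                  cross_group = FALSE))
  }
  ends <- vapply(members, function(m) db$records[[m]]$coverage_end, integer(1L))
  result(members[which.max(ends)], fallback = TRUE, cross_group = FALSE)
}

#' Account newly resolved nucleotides
#'
#' Computes how many coding and non-coding nucleotides a newly resolved record
#' adds over what was previously known: coding counts sum the lengths of newly
#' resolved exons; non-coding counts sum newly resolved UTR/intron lengths,
#' including a partial 3'UTR extension beyond the previous coverage end.
#'
#' @param previously_known Character vector of feature ids that were already
#'   resolved (may be empty).
#' @param new_record The newly resolved `hla_allele_record`.
#' @param model The locus `hla_gene_model`.
#' @param prev_coverage_end Previous highest known genomic position (defaults
#'   to the end of the last previously known feature); relevant when the
#'   3'UTR was only partially known.
#' @return An object of class `hla_addition_account`: `coding_added`,
#'   `noncoding_added` and a `per_feature` breakdown. A record that resolves
#'   nothing new yields a zero account.
#' @examples
#' # HLA-A with previously known exons 2 and 3, now full-length:
#' # coding_added is 552 (exons 1, 4, 5, 6, 7, 8)
#' @export
count_added_nucleotides <- function(previously_known, new_record, model,
                                    prev_coverage_end = NULL) {
  new_feats <- new_record$known_features
  if (!all(previously_known %in% new_feats)) {
    stop("previously known features must be a subset of the new record's")
  }
  ft <- model_feature_table(model)
  ft <- ft[ft$length > 0L, , drop = FALSE]
  newly <- setdiff(new_feats, previously_known)
  per <- integer(0L)
  for (f in newly) {
    row <- match(f, ft$feature)
    len <- ft$length[row]
    if (f == "UTR3" && new_record$coverage_end < ft$end[row]) {
      len <- len - (ft$end[row] - new_record$coverage_end)
    }
    per[[f]] <- len
  }
  # partial 3'UTR extension of an already partially known UTR3
  if ("UTR3" %in% previously_known && "UTR3" %in% new_feats) {
    row <- match("UTR3", ft$feature)
    if (is.null(prev_coverage_end)) prev_coverage_end <- ft$end[row]
    ext <- min(new_record$coverage_end, ft$end[row]) - prev_coverage_end
    if (ext > 0L) per[["UTR3"]] <- ext
  }
  exon <- grepl("^E[0-9]+$", names(per))
  acc <- structure(
    list(coding_added = sum(per[exon]),
         noncoding_added = sum(per[!exon]),
         per_feature = per),
    class = "hla_addition_account"
  )
  acc
}

#' @export
print.hla_addition_account <- function(x, ...) {
  cat("<hla_addition_account> coding ", x$coding_added, " nt, non-coding ",
      x$noncoding_added, " nt\n", sep = "")
  invisible(x)
}
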