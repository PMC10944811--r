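#' Read a FASTA file
#'
#' @param path Path to a FASTA file of nucleotide sequences (IUPAC codes,
#'   case-insensitive).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("invalid FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

extension_table_ids <- c("table1A", "table1B", "table2", "table5")

#' Load a packaged allele-extension table
#'
#' The package ships machine-readable transcriptions of the curated submission
#' tables for extended full-length HLA alleles: `table1A` (19 class I alleles
#' extended to full length), `table1B` (7 class II alleles), `table2`
#' (non-coding differences against the reference allele) and `table5` (47
#' class I alleles extended with 5'/3' UTR sequence).
#'
#' @param id One of `"table1A"`, `"table1B"`, `"table2"`, `"table5"`.
#' @return A data frame of class `hla_extension_table`; numeric columns are
#'   the added-nucleotide counts, `noncoding_diff` flags alleles whose
#'   non-coding sequence differs from the reference, `differences` holds the
#'   rendered per-position difference lists (`;`-separated).
#' @examples
#' nrow(load_extension_table("table1A"))  # 19
#' @export
load_extension_table <- function(id) {
  id <- match.arg(id, extension_table_ids)
  path <- system.file("extdata", "tables", paste0(id, ".tsv"),
                      package = "hlafull")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture missing: ", id)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = character(0L))
  if (!nrow(tab)) stop("corrupt fixture (no rows): ", id)
  class(tab) <- c("hla_extension_table", class(tab))
  attr(tab, "table_id") <- id
  tab
}

#' Summarize an extension table
#'
#' Re-derives the headline totals of an extension table: sums of coding and
#' non-coding nucleotides added, and counts of alleles with non-coding
#' differences, 5'UTR additions and 3'UTR differences. Sums are always
#' recomputed from the rows, never stored.
#'
#' @param rows A data frame from [load_extension_table()] (or any subset of
#'   its rows).
#' @return A list of totals; entries whose source column is absent are 0.
#' @examples
#' summarize_extension_tables(load_extension_table("table1A"))$coding_added_sum
#' @export
summarize_extension_tables <- function(rows) {
  col_sum <- function(col) {
    if (col %in% names(rows)) sum(as.integer(rows[[col]])) else 0L
  }
  col_count <- function(col, f) {
    if (col %in% names(rows)) sum(f(rows[[col]])) else 0L
  }
  n_diff <- col_count("noncoding_diff", function(x) as.integer(x) == 1L)
  has_diff_list <- col_count("differences", function(x) nzchar(trimws(x)))
  list(
    n_rows = nrow(rows),
    coding_added_sum = col_sum("coding_added"),
    noncoding_added_sum = col_sum("noncoding_added") +
      col_sum("utr5_added") + col_sum("utr3_added"),
    utr5_added_sum = col_sum("utr5_added"),
    utr3_added_sum = col_sum("utr3_added"),
    n_with_noncoding_difference = n_diff,
    n_without_noncoding_difference =
      if ("noncoding_diff" %in% names(rows)) nrow(rows) - n_diff else 0L,
    n_with_utr5 = col_count("utr5_added", function(x) as.integer(x) > 0L),
    n_with_utr3_differences =
      if ("utr3_added" %in% names(rows)) has_diff_list else 0L
  )
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @param digits Significant digits for branch lengths (default 6).
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L) {
    stop("cannot write an empty or non-phylo tree")
  }
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- signif(tree$edge.length, digits)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  ape::read.tree(path)
}

#' Write a tabular report as TSV
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV report
#' @param path Path to a TSV written by [write_report()].
#' @return A data frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = character(0L))
}
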