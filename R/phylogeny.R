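#' Mask a multiple alignment to a coordinate window
#'
#' Restricts an alignment to a genomic window and removes the columns of
#' excluded features (e.g. exon 2 when lineage signal should come from
#' non-coding sequence only). Columns are addressed by genomic position, so
#' the alignment must be columnar on model coordinates (no-indel synthetic
#' families, or reference-anchored projections).
#'
#' @param msa Named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = alleles).
#' @param model The locus `hla_gene_model`.
#' @param window Genomic interval `c(start, end)` to keep (default: the full
#'   model span).
#' @param exclude Character vector of feature ids whose columns are dropped.
#' @param positions Genomic positions of the columns (default: the model span
#'   positions, requiring full-span rows).
#' @return An object of class `hla_masked_alignment`: `seqs` (character
#'   matrix) and `positions` (genomic positions of the retained columns).
#' @export
mask_alignment <- function(msa, model, window = NULL, exclude = character(),
                           positions = NULL) {
  mat <- as_seq_matrix(msa)
  utr5 <- model$lengths[["UTR5"]]
  if (is.null(positions)) {
    if (ncol(mat) != model_span_length(model)) {
      stop("alignment width ", ncol(mat), " does not match the model span; ",
           "supply explicit column positions")
    }
    positions <- index_to_genomic(seq_len(ncol(mat)), utr5)
  }
  if (length(positions) != ncol(mat)) {
    stop("positions must match the alignment width")
  }
  keep <- rep(TRUE, ncol(mat))
  if (!is.null(window)) {
    span <- model_span(model)
    if (window[1L] < span[1L] || window[2L] > span[2L]) {
      stop("window outside the model span")
    }
    keep <- keep & positions >= window[1L] & positions <= window[2L]
  }
  if (length(exclude)) {
    ft <- model_feature_table(model)
    for (f in exclude) {
      row <- match(f, ft$feature)
      if (is.na(row)) stop("unknown feature in exclude: ", f)
      if (!is.na(ft$start[row])) {
        keep <- keep & !(positions >= ft$start[row] & positions <= ft$end[row])
      }
    }
  }
  if (!any(keep)) stop("mask removes every column")
  structure(list(seqs = mat[, keep, drop = FALSE], positions = positions[keep]),
            class = "hla_masked_alignment")
}

as_seq_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  stopifnot(is.character(msa), !is.null(names(msa)))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("aligned sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(mat) <- names(msa)
  mat
}

#' Square-root percentage-difference distance between two aligned rows
#'
#' The distance between two aligned sequences is the square root of their
#' mismatch fraction: `sqrt(mismatches / comparable sites)`, where a site is
#' comparable when both rows carry a plain, unambiguous base (gap or IUPAC
#' ambiguity in either row removes the column from both counts - pairwise
#' deletion). The fraction lies in `[0, 1]`, so distances are in
#' sqrt-fraction units.
#'
#' @param row_a,row_b Equal-length aligned sequence strings (or character
#'   vectors).
#' @return Non-negative distance; 0 for identical rows.
#' @examples
#' pairwise_distance("AC-GT", "ACAGA")  # 1 mismatch over 4 sites -> 0.5
#' @export
pairwise_distance <- function(row_a, row_b) {
  a <- if (length(row_a) > 1L) row_a else strsplit(toupper(row_a), "")[[1L]]
  b <- if (length(row_b) > 1L) row_b else strsplit(toupper(row_b), "")[[1L]]
  if (length(a) != length(b)) stop("rows must have equal length")
  plain <- function(x) x %in% c("A", "C", "G", "T")
  comp <- plain(a) & plain(b)
  n <- sum(comp)
  if (n == 0L) stop("distance undefined: zero comparable sites")
  sqrt(sum(a[comp] != b[comp]) / n)
}

#' Pairwise distance matrix of an alignment
#'
#' Applies [pairwise_distance()] to every pair of rows.
#'
#' @param msa Named character vector, character matrix, or an
#'   `hla_masked_alignment`.
#' @return An object of class `hla_distance_matrix`: `ids`, symmetric
#'   zero-diagonal matrix `d`, and the per-pair comparable-site counts
#'   `n_comparable`.
#' @export
distance_matrix <- function(msa) {
  if (inherits(msa, "hla_masked_alignment")) msa <- msa$seqs
  mat <- as_seq_matrix(msa)
  ids <- rownames(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  nc <- matrix(ncol(mat), n, n, dimnames = list(ids, ids))
  plain <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        comp <- plain[i, ] & plain[j, ]
        m <- sum(comp)
        if (m == 0L) stop("distance undefined for pair ", ids[i], "/", ids[j])
        d[i, j] <- d[j, i] <- sqrt(sum(mat[i, comp] != mat[j, comp]) / m)
        nc[i, j] <- nc[j, i] <- m
      }
    }
  }
  structure(list(ids = ids, d = d, n_comparable = nc),
            class = "hla_distance_matrix")
}

#' @export
print.hla_distance_matrix <- function(x, ...) {
  cat("<hla_distance_matrix> ", length(x$ids), " sequences\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' @export
as.dist.hla_distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Build a lineage tree from a distance matrix
#'
#' Neighbor-joining (default) or UPGMA construction on sqrt-fraction
#' distances. Negative estimated branch lengths are clamped to zero.
#'
#' @param dm An `hla_distance_matrix` (or a plain symmetric matrix with
#'   dimnames).
#' @param method `"nj"` (default) or `"upgma"`.
#' @return An `ape::phylo` tree whose tips are the matrix ids.
#' @export
build_tree <- function(dm, method = c("nj", "upgma")) {
  method <- match.arg(method)
  d <- if (inherits(dm, "hla_distance_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("tree construction needs at least 3 sequences")
  tree <- if (method == "nj") {
    ape::nj(stats::as.dist(d))
  } else {
    ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Extract k leaf clusters from a tree
#'
#' Cuts the tree by removing its longest edges - internal edges first (in
#' decreasing length, ties by edge index), then pendant edges - until the
#' leaves fall into `k` connected components. With well-separated lineages the
#' removed edges are the long inter-lineage internal edges, so the components
#' are the lineages.
#'
#' @param tree An `ape::phylo` tree.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return A list of `k` character vectors (leaf labels), ordered by their
#'   first leaf.
#' @export
extract_clusters <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  if (k < 1L || k > n_tip) stop("k must be between 1 and the leaf count")
  edges <- tree$edge
  lens <- tree$edge.length
  internal <- edges[, 1L] > n_tip & edges[, 2L] > n_tip
  priority <- order(!internal, -lens, seq_along(lens))
  n_node <- max(edges)

  leaf_components <- function(removed) {
    comp <- seq_len(n_node)
    find <- function(x) {
      while (comp[x] != x) x <- comp[x]
      x
    }
    for (e in seq_len(nrow(edges))) {
      if (removed[e]) next
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) comp[a] <- b
    }
    vapply(seq_len(n_tip), find, integer(1L))
  }

  removed <- rep(FALSE, nrow(edges))
  roots <- leaf_components(removed)
  # removing a pendant edge of a single-leaf component does not raise the
  # number of leaf-bearing components, so remove until exactly k remain
  for (e in priority) {
    if (length(unique(roots)) >= k) break
    removed[e] <- TRUE
    roots <- leaf_components(removed)
  }
  groups <- split(tree$tip.label, roots)
  groups <- groups[order(vapply(groups, function(g) min(g), character(1L)))]
  unname(groups)
}
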