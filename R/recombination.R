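#' Informative sites between a reference and a candidate donor
#'
#' An informative site is a position where the two candidate parental alleles
#' (reference and donor) carry different, unambiguous bases, so the query's
#' base indicates its local ancestry. Positions where either parent is
#' unknown, ambiguous or gapped are excluded; a query base matching neither
#' parent is classified `matches_neither` (a candidate residual point
#' mutation). All three sequences must already be projected onto common
#' reference coordinates.
#'
#' @param query,reference,donor Equal-length sequence strings on common
#'   coordinates.
#' @param positions Genomic positions of the columns (integer vector of the
#'   same length); defaults to `1..n`.
#' @return A data frame of class `hla_informative_sites` with columns
#'   `position`, `ref_base`, `donor_base`, `query_base`, `state`
#'   (`matches_ref` / `matches_donor` / `matches_neither`).
#' @export
informative_sites <- function(query, reference, donor, positions = NULL) {
  q <- strsplit(toupper(query), "")[[1L]]
  r <- strsplit(toupper(reference), "")[[1L]]
  d <- strsplit(toupper(donor), "")[[1L]]
  n <- length(r)
  if (length(q) != n || length(d) != n) {
    stop("query, reference and donor must be on common coordinates ",
         "(equal lengths)")
  }
  if (is.null(positions)) positions <- seq_len(n)
  if (length(positions) != n) stop("positions must match the sequence length")
  plain <- function(x) x %in% c("A", "C", "G", "T")
  keep <- plain(r) & plain(d) & plain(q) & r != d
  state <- ifelse(q[keep] == r[keep], "matches_ref",
                  ifelse(q[keep] == d[keep], "matches_donor",
                         "matches_neither"))
  res <- data.frame(position = positions[keep], ref_base = r[keep],
                    donor_base = d[keep], query_base = q[keep],
                    state = state, stringsAsFactors = FALSE)
  class(res) <- c("hla_informative_sites", class(res))
  res
}

#' Segment the parental path of a query across informative sites
#'
#' Assigns each informative site to the parent it matches and reports the
#' resulting mosaic: maximal runs of same-parent sites become segments, and
#' the open interval between the last site of one segment and the first site
#' of the next is a breakpoint interval (the true crossover lies somewhere
#' inside). Because every retained site matches exactly one parent, this
#' run-length path is the segmentation with the global minimum number of
#' source switches. Sites matching neither parent are set aside as residual
#' point mutations, not segmented.
#'
#' @param sites An `hla_informative_sites` data frame.
#' @return An object of class `hla_recombination_report`: `segments` (data
#'   frame with `source`, `from`, `to`, `n_sites`), `breakpoint_intervals`
#'   (data frame with open-interval bounds `lower`, `upper`),
#'   `residual_positions` and `n_switches`.
#' @export
segment_parental_path <- function(sites) {
  stopifnot(is.data.frame(sites))
  if (!nrow(sites)) stop("no informative sites to segment")
  sites <- sites[order(sites$position), , drop = FALSE]
  residual <- sites$position[sites$state == "matches_neither"]
  core <- sites[sites$state != "matches_neither", , drop = FALSE]
  if (!nrow(core)) {
    stop("no call: every informative site matches neither parent")
  }
  src <- ifelse(core$state == "matches_ref", "reference", "donor")
  runs <- rle(src)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segments <- data.frame(
    source = runs$values,
    from = core$position[starts],
    to = core$position[ends],
    n_sites = runs$lengths,
    stringsAsFactors = FALSE
  )
  k <- nrow(segments)
  if (k > 1L) {
    breakpoints <- data.frame(lower = segments$to[-k],
                              upper = segments$from[-1L])
  } else {
    breakpoints <- data.frame(lower = integer(0L), upper = integer(0L))
  }
  structure(
    list(segments = segments, breakpoint_intervals = breakpoints,
         residual_positions = residual, n_switches = k - 1L),
    class = "hla_recombination_report"
  )
}

#' @export
print.hla_recombination_report <- function(x, ...) {
  cat("<hla_recombination_report> ", nrow(x$segments), " segment(s), ",
      x$n_switches, " switch(es), ", length(x$residual_positions),
      " residual mutation(s)\n", sep = "")
  if (x$n_switches > 0L) {
    cat("  breakpoints ", render_breakpoints(x), "\n", sep = "")
  }
  invisible(x)
}

#' Render breakpoint intervals in report style
#'
#' @param report An `hla_recombination_report`.
#' @return A string such as `"between 695-726 and 810-900"`, or
#'   `"no recombination"` for a single-segment report.
#' @export
render_breakpoints <- function(report) {
  bp <- report$breakpoint_intervals
  if (!nrow(bp)) return("no recombination")
  paste0("between ",
         paste(paste0(bp$lower, "-", bp$upper), collapse = " and "))
}

#' Scan a panel of candidate donor alleles for gene conversion
#'
#' For each candidate donor the query is segmented against
#' (reference, donor) informative sites; donors are ranked by fewest residual
#' mutations (query positions matching neither the reference nor the donor
#' mosaic), then fewest switches, then allele-name order. A conversion is
#' called only when the best report has at least one switch and every segment
#' is supported by at least `min_sites_per_segment` informative sites; a
#' single shared site is indistinguishable from a point mutation. All donors
#' tied with the best are listed (dual attribution).
#'
#' @param query,reference Sequence strings on common coordinates.
#' @param panel Named character vector of candidate donor sequences (same
#'   coordinates).
#' @param positions Genomic positions of the columns (default `1..n`).
#' @param min_sites_per_segment Minimum informative sites per segment for a
#'   call (default 2).
#' @return An object of class `hla_convscan`: `ranking` (data frame with
#'   `donor`, `n_residual`, `n_switches`, `supported`), `reports` (per-donor
#'   recombination reports or NULL), `called` (logical) and `best` (character
#'   vector of co-optimal donors when called).
#' @export
scan_donor_panel <- function(query, reference, panel, positions = NULL,
                             min_sites_per_segment = 2L) {
  if (!length(panel)) stop("donor panel is empty")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel donors must be named")
  }
  q <- strsplit(toupper(query), "")[[1L]]
  r <- strsplit(toupper(reference), "")[[1L]]
  plain <- function(x) x %in% c("A", "C", "G", "T")
  reports <- vector("list", length(panel))
  names(reports) <- names(panel)
  n_residual <- integer(length(panel))
  n_switches <- integer(length(panel))
  supported <- logical(length(panel))
  for (i in seq_along(panel)) {
    d <- strsplit(toupper(panel[[i]]), "")[[1L]]
    sites <- informative_sites(query, reference, panel[[i]], positions)
    # residuals: query differs from both parents anywhere comparable,
    # including plain point mutations at non-informative positions
    comp <- plain(q) & plain(r) & plain(d)
    n_residual[i] <- sum(comp & q != r & q != d)
    rep_i <- if (nrow(sites)) {
      tryCatch(segment_parental_path(sites), error = function(e) NULL)
    } else NULL
    reports[[i]] <- rep_i
    if (!is.null(rep_i)) {
      n_switches[i] <- rep_i$n_switches
      supported[i] <- rep_i$n_switches >= 1L &&
        all(rep_i$segments$n_sites >= min_sites_per_segment)
    }
  }
  ord <- order(n_residual, n_switches, allele_name_key_safe(names(panel)))
  ranking <- data.frame(donor = names(panel)[ord],
                        n_residual = n_residual[ord],
                        n_switches = n_switches[ord],
                        supported = supported[ord],
                        stringsAsFactors = FALSE)
  best_row <- ranking[1L, ]
  called <- isTRUE(best_row$supported)
  best <- character(0L)
  if (called) {
    ties <- ranking$n_residual == best_row$n_residual &
      ranking$n_switches == best_row$n_switches & ranking$supported
    best <- ranking$donor[ties]
  }
  structure(list(ranking = ranking, reports = reports, called = called,
                 best = best),
            class = "hla_convscan")
}

# allele-name order when names parse; plain lexicographic otherwise
allele_name_key_safe <- function(x) {
  vapply(x, function(nm) {
    tryCatch(allele_name_key(nm), error = function(e) nm)
  }, character(1L))
}

#' @export
print.hla_convscan <- function(x, ...) {
  if (x$called) {
    cat("<hla_convscan> conversion called; donor(s): ",
        paste(x$best, collapse = "/"), "\n", sep = "")
  } else {
    cat("<hla_convscan> no conversion called\n")
  }
  invisible(x)
}
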