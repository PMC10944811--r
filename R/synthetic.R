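#' Specification for a synthetic allele family
#'
#' Describes a multi-lineage allele family with known ground truth: a root
#' sequence drawn over the gene-model span, lineage founders mutated from the
#' root at the between-lineage rate, and lineage members mutated from their
#' founder at the within-lineage rate. Substitutions are drawn uniformly over
#' the three alternative bases (no transition/transversion bias). The default
#' indel rate is 0, so family members are columnar on model coordinates.
#'
#' @param model An `hla_gene_model`.
#' @param n_lineages Number of lineages (allele groups).
#' @param alleles_per_lineage Members per lineage.
#' @param between Between-lineage per-site substitution probability, in
#'   `[0, 0.2]`.
#' @param within Within-lineage per-site substitution probability, in
#'   `[0, 0.2]`.
#' @param indel_rate Per-site indel probability (default 0).
#' @param seed Mandatory RNG seed for reproducibility.
#' @return An object of class `hla_family_spec`.
#' @export
family_spec <- function(model, n_lineages = 3L, alleles_per_lineage = 4L,
                        between = 0.05, within = 0.01, indel_rate = 0,
                        seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory for a reproducible family")
  }
  rates <- c(between = between, within = within, indel_rate = indel_rate)
  if (any(rates < 0) || any(rates > 0.2)) {
    stop("rates must lie in [0, 0.2]")
  }
  stopifnot(inherits(model, "hla_gene_model"),
            n_lineages >= 1L, alleles_per_lineage >= 1L)
  structure(list(model = model, n_lineages = as.integer(n_lineages),
                 alleles_per_lineage = as.integer(alleles_per_lineage),
                 between = between, within = within, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "hla_family_spec")
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence at given substitution and indel rates
#'
#' Each site substitutes with probability `sub_rate` to one of the three
#' alternative bases (uniformly); with probability `indel_rate` a site hosts
#' a single-base insertion or deletion (equiprobable). Uses the current RNG
#' stream.
#'
#' @param sequence Nucleotide string.
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Per-site indel probability (default 0).
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(sequence, sub_rate, indel_rate = 0) {
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  hit <- stats::runif(n) < sub_rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1L))
  }
  if (indel_rate > 0) {
    ind <- stats::runif(n) < indel_rate
    if (any(ind)) {
      pieces <- as.list(chars)
      for (i in which(ind)) {
        if (stats::runif(1L) < 0.5) {
          pieces[[i]] <- c(chars[i], sample(c("A", "C", "G", "T"), 1L))
        } else {
          pieces[[i]] <- character(0L)
        }
      }
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic allele family with known truth
#'
#' @param spec An `hla_family_spec`.
#' @return A list with `db` (an `hla_allele_db` of full-length records named
#'   `<locus>*<lineage>:<member>`, so the allele group equals the lineage)
#'   and `truth` (data frame `allele`, `lineage`; plus the `root` and founder
#'   sequences as attributes). Deterministic for a given seed.
#' @examples
#' m <- gene_model("TOY", c("UTR5", "E1", "I1", "E2", "UTR3"),
#'                 c(10, 30, 40, 50, 10))
#' fam <- generate_family(family_spec(m, 2, 2, 0.05, 0.01, seed = 1))
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "hla_family_spec"))
  model <- spec$model
  with_seed(spec$seed, {
    root <- random_sequence(model_span_length(model))
    records <- list()
    truth <- list()
    founders <- character(spec$n_lineages)
    for (l in seq_len(spec$n_lineages)) {
      founders[l] <- mutate_sequence(root, spec$between)
      for (m in seq_len(spec$alleles_per_lineage)) {
        seq_m <- mutate_sequence(founders[l], spec$within, spec$indel_rate)
        name <- sprintf("%s*%02d:%02d", model$locus, l, m)
        records[[name]] <- allele_record(
          name, seq_m, model, validate = spec$indel_rate == 0
        )
        truth[[name]] <- data.frame(allele = name, lineage = l,
                                    stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    attr(truth, "root") <- root
    attr(truth, "founders") <- founders
    list(db = allele_db(unname(records),
                        stats::setNames(list(model), model$locus)),
         truth = truth)
  })
}

#' Build a recombinant mosaic of two parent sequences
#'
#' Copies `parent_a` and exchanges the tracts delimited by the breakpoints
#' with `parent_b`, alternating at each breakpoint (so two breakpoints give
#' the a|b|a mosaic of a double crossover). Breakpoints are genomic
#' positions: the switch happens immediately after each breakpoint position.
#'
#' @param parent_a,parent_b `hla_allele_record`s or sequence strings of equal
#'   length in common coordinates.
#' @param breakpoints Strictly increasing genomic positions.
#' @param model The locus `hla_gene_model` (required when parents are
#'   records, for coordinate conversion).
#' @param name Allele name for the recombinant record (default
#'   `<locus>*99:01`).
#' @return A list with `record` (or `sequence` when inputs were strings) and
#'   `truth` (parents and true breakpoints).
#' @export
make_recombinant <- function(parent_a, parent_b, breakpoints, model = NULL,
                             name = NULL) {
  a_rec <- inherits(parent_a, "hla_allele_record")
  a <- if (a_rec) parent_a$sequence else toupper(parent_a)
  b <- if (inherits(parent_b, "hla_allele_record")) parent_b$sequence
       else toupper(parent_b)
  if (nchar(a) != nchar(b)) {
    stop("parents must have equal length in common coordinates")
  }
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) && any(diff(breakpoints) <= 0L)) {
    stop("breakpoints must be strictly increasing")
  }
  n <- nchar(a)
  if (!is.null(model)) {
    cuts <- genomic_to_index(breakpoints, model$lengths[["UTR5"]])
  } else {
    cuts <- breakpoints
  }
  if (length(cuts) && (any(cuts < 1L) || any(cuts >= n))) {
    stop("breakpoint outside the parental span")
  }
  bounds <- c(0L, cuts, n)
  chars_a <- strsplit(a, "")[[1L]]
  chars_b <- strsplit(b, "")[[1L]]
  out <- chars_a
  take_b <- FALSE
  for (s in seq_len(length(bounds) - 1L)) {
    if (take_b) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      out[idx] <- chars_b[idx]
    }
    take_b <- !take_b
  }
  seq_out <- paste(out, collapse = "")
  truth <- list(
    parent_a = if (a_rec) format(parent_a$name) else "parent_a",
    parent_b = if (inherits(parent_b, "hla_allele_record"))
      format(parent_b$name) else "parent_b",
    breakpoints = breakpoints
  )
  if (!is.null(model)) {
    if (is.null(name)) name <- sprintf("%s*99:01", model$locus)
    return(list(record = allele_record(name, seq_out, model), truth = truth))
  }
  list(sequence = seq_out, truth = truth)
}

#' Degrade a record to a partial-coverage state
#'
#' Restricts a record to a kept feature subset, emulating the
#' partially-resolved state of database alleles (e.g. exons 2 and 3 only for
#' class I) so that re-extension round-trips through
#' [count_added_nucleotides()].
#'
#' @param record A full `hla_allele_record`.
#' @param keep Non-empty subset of the record's known features.
#' @param model The locus `hla_gene_model`.
#' @return The degraded `hla_allele_record`.
#' @export
degrade_to_partial <- function(record, keep, model) {
  if (!length(keep)) stop("keep must name at least one feature")
  if (!all(keep %in% record$known_features)) {
    stop("keep must be a subset of the record's known features")
  }
  keep <- model$features[model$features %in% keep]
  seqs <- vapply(keep, function(f) record_feature_sequence(record, model, f),
                 character(1L))
  ft <- model_feature_table(model)
  last <- keep[length(keep)]
  cov <- if (last == "UTR3") record$coverage_end else
    ft$end[match(last, ft$feature)]
  allele_record(record$name, paste(seqs, collapse = ""), model,
                known_features = keep, coverage_end = cov)
}
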