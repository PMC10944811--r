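# Independent oracles and small fixture builders used across the suite.

# Gotoh affine-gap global alignment score, written independently of the
# package's aligner: gap of length L costs gap_open + gap_ext * L.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 4, gap_ext = 0.5) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                               X[i, j + 1L] - gap_ext,
                               Y[i, j + 1L] - gap_open - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                               Y[i + 1L, j] - gap_ext,
                               X[i + 1L, j] - gap_open - gap_ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Minimal number of source switches for a site-state pattern, by dynamic
# programming over (position, current source) with every site required to
# match its assigned source.
oracle_min_switches <- function(states) {
  INF <- 1e9
  cr <- if (states[1L] == "R") 0 else INF
  cd <- if (states[1L] == "D") 0 else INF
  for (s in states[-1L]) {
    nr <- min(cr, cd + 1) + if (s == "R") 0 else INF
    nd <- min(cd, cr + 1) + if (s == "D") 0 else INF
    cr <- nr; cd <- nd
  }
  min(cr, cd)
}

# Exhaustive enumeration over all breakpoint subsets (small n only): the
# minimal number of switches among alternating segmentations matching every
# site.
oracle_min_switches_enum <- function(states) {
  n <- length(states)
  best <- Inf
  for (mask in 0:(2^max(n - 1L, 0L) - 1L)) {
    switches <- which(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)) > 0L)
    for (first in c("R", "D")) {
      src <- first
      ok <- states[1L] == src
      for (i in seq_len(n)[-1L]) {
        if ((i - 1L) %in% switches) src <- if (src == "R") "D" else "R"
        if (states[i] != src) { ok <- FALSE; break }
      }
      if (ok) best <- min(best, length(switches))
    }
  }
  best
}

# Naive position-scan homopolymer finder.
oracle_homopolymers <- function(sequence, min_len) {
  chars <- strsplit(sequence, "")[[1L]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    j <- i
    while (j < length(chars) && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_len) {
      out[[length(out) + 1L]] <- data.frame(start = i, base = chars[i],
                                            length = j - i + 1L,
                                            stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), base = character(), length = integer(),
                  stringsAsFactors = FALSE)
}

# sites data frame from a state pattern (positions 10, 20, 30, ...)
sites_from_states <- function(states) {
  data.frame(position = 10L * seq_along(states),
             ref_base = "A", donor_base = "G",
             query_base = ifelse(states == "R", "A",
                                 ifelse(states == "D", "G", "C")),
             state = ifelse(states == "R", "matches_ref",
                            ifelse(states == "D", "matches_donor",
                                   "matches_neither")),
             stringsAsFactors = FALSE)
}

# a small synthetic locus used where span size does not matter
toy_model <- function() {
  gene_model("SYN", c("UTR5", "E1", "I1", "E2", "I2", "E3", "UTR3"),
             c(10, 90, 300, 270, 200, 120, 110))
}

# partitions as sets of sets, for cluster comparison
same_partition <- function(a, b) {
  norm <- function(p) {
    sort(unname(vapply(p, function(g) paste(sort(g), collapse = ","),
                       character(1L))))
  }
  identical(norm(a), norm(b))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# substitute single bases of a sequence at 1-based string offsets
substitute_at <- function(seq, offsets, bases) {
  chars <- strsplit(seq, "")[[1L]]
  chars[offsets] <- bases
  paste(chars, collapse = "")
}

# substitute to a different base (cyclic), returning the new sequence
flip_base <- function(seq, offset) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1L]]
  chars[offset] <- bases[(match(chars[offset], bases)) %% 4L + 1L]
  paste(chars, collapse = "")
}

# genomic position -> 1-based string index for a full-span record
genomic_to_index_for_test <- function(pos, model) {
  utr5 <- model$lengths[["UTR5"]]
  if (pos > 0L) pos + utr5 else pos + utr5 + 1L
}

# genomic positions of all columns of a full-span record
genomic_positions_for_test <- function(model) {
  utr5 <- model$lengths[["UTR5"]]
  i <- seq_len(model_span_length(model))
  ifelse(i > utr5, i - utr5, i - utr5 - 1L)
}
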