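#' Parse an HLA allele name
#'
#' HLA alleles are named as `<locus>*<field1>:<field2>[:<field3>[:<field4>]]`
#' with an optional trailing expression suffix (`N`, `Q`, `L`, ...) and an
#' optional `HLA-` prefix, e.g. `"B*53:06"` or `"HLA-DQA1*01:02:01:04"`. The
#' first numeric field identifies the allele group.
#'
#' @param text A single allele name string.
#' @return An object of class `hla_allele_name` with elements `locus`
#'   (character), `fields` (integer vector of length 1--4) and `suffix`
#'   (character, `""` when absent). Formatting the result reproduces the
#'   input (minus any `HLA-` prefix).
#' @examples
#' parse_allele_name("B*53:06")
#' parse_allele_name("HLA-DQA1*01:02:01:04")
#' @export
parse_allele_name <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("allele name must be a single character string")
  }
  raw <- trimws(text)
  x <- sub("^HLA-", "", raw)
  if (!grepl("*", x, fixed = TRUE)) {
    stop("malformed allele name (no '*' separator): ", sQuote(raw))
  }
  parts <- strsplit(x, "*", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L])) {
    stop("malformed allele name: ", sQuote(raw))
  }
  locus <- parts[1L]
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", locus)) {
    stop("malformed locus ", sQuote(locus), " in ", sQuote(raw))
  }
  rest <- parts[2L]
  suffix <- ""
  if (grepl("[A-Za-z]$", rest)) {
    suffix <- substring(rest, nchar(rest))
    rest <- substring(rest, 1L, nchar(rest) - 1L)
  }
  fields <- strsplit(rest, ":", fixed = TRUE)[[1L]]
  if (length(fields) < 1L || length(fields) > 4L) {
    stop("allele name must have 1-4 numeric fields: ", sQuote(raw))
  }
  bad <- fields[!grepl("^[0-9]+$", fields)]
  if (length(bad)) {
    stop("non-numeric allele-name field ", sQuote(bad[1L]), " in ",
         sQuote(raw))
  }
  structure(
    list(locus = locus, fields = as.integer(fields), suffix = suffix,
         field_text = fields),
    class = "hla_allele_name"
  )
}

#' @export
format.hla_allele_name <- function(x, ...) {
  paste0(x$locus, "*", paste(x$field_text, collapse = ":"), x$suffix)
}

#' @export
print.hla_allele_name <- function(x, ...) {
  cat("<hla_allele_name> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.hla_allele_name <- function(x, ...) format(x)

as_allele_name <- function(x) {
  if (inherits(x, "hla_allele_name")) x else parse_allele_name(x)
}

#' Allele group of an HLA allele
#'
#' Two alleles belong to the same allele group when they share the locus and
#' the first numeric name field (e.g. all `B*53` alleles). Reference selection
#' always starts within the query's allele group.
#'
#' @param name An `hla_allele_name` or a string parseable as one.
#' @return A group key string such as `"B*53"`.
#' @examples
#' allele_group("B*53:06")           # "B*53"
#' allele_group("B*51:01:01:04")     # "B*51"
#' @export
allele_group <- function(name) {
  name <- as_allele_name(name)
  paste0(name$locus, "*", name$field_text[1L])
}

#' Sort key for allele-name ordering
#'
#' Ordering is lexicographic on the integer fields (so `A*03:01:01:01`
#' precedes `A*03:13`); a name that is a prefix of another precedes it.
#' Expression suffixes are ignored for ordering.
#'
#' @param names A list of `hla_allele_name` objects or a character vector.
#' @return A character vector that sorts in allele order.
#' @export
allele_name_key <- function(names) {
  if (is.character(names)) names <- lapply(names, parse_allele_name)
  if (inherits(names, "hla_allele_name")) names <- list(names)
  vapply(names, function(nm) {
    f <- c(nm$fields, rep(-1L, 4L - length(nm$fields)))
    paste0(nm$locus, "|", paste(formatC(f + 1L, width = 6L, flag = "0"),
                                collapse = ":"))
  }, character(1L))
}

#' Sort allele names
#'
#' @param names Character vector of allele names.
#' @return The input sorted in allele order (locus, then integer fields).
#' @examples
#' sort_allele_names(c("A*03:13", "A*03:01:01:01"))
#' @export
sort_allele_names <- function(names) {
  names[order(allele_name_key(names), names)]
}

#' Compare two allele names
#'
#' @param a,b Allele names (strings or `hla_allele_name`).
#' @return -1, 0 or 1 as `a` precedes, equals or follows `b`.
#' @export
compare_allele_names <- function(a, b) {
  ka <- allele_name_key(list(as_allele_name(a)))
  kb <- allele_name_key(list(as_allele_name(b)))
  if (ka < kb) -1L else if (ka > kb) 1L else 0L
}
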