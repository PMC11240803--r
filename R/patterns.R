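#' Sequential behaviour patterns
#'
#' A pattern is an ordered series of *elements*; each element is an ordered
#' run of behaviour codes (repeats allowed, e.g. `P,F,P`) that must embed
#' within a single observation window. Patterns are printed in the
#' angle-bracket/brace dialect used for behavioural sequence tables:
#' `<{Ld,P} {Ld,P,F}> (n = 2)`.
#'
#' @param elements A list of non-empty character vectors of behaviour codes.
#' @return An object of class `behavior_pattern` (a list of character
#'   vectors).
#' @examples
#' p <- behavior_pattern(list(c("P", "F", "P"), c("Ld", "P")))
#' format(p)
#' sequence_size(p)  # 2 elements
#' @export
behavior_pattern <- function(elements) {
  if (is.character(elements)) elements <- list(elements)
  stopifnot(is.list(elements), length(elements) >= 1L)
  elements <- lapply(elements, as.character)
  if (any(vapply(elements, length, 1L) == 0L)) {
    stop("pattern elements must be non-empty", call. = FALSE)
  }
  structure(elements, class = "behavior_pattern")
}

#' @export
format.behavior_pattern <- function(x, count = NULL, ...) {
  body <- paste0(vapply(x, function(el) {
    paste0("{", paste(el, collapse = ","), "}")
  }, ""), collapse = " ")
  out <- paste0("<", body, ">")
  if (!is.null(count) && !is.na(count)) out <- paste0(out, " (n = ", count, ")")
  out
}

#' @export
print.behavior_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Format a pattern in table notation
#'
#' @param pattern A [behavior_pattern()].
#' @param count Optional integer count appended as `(n = k)`.
#' @return A single string such as `"<{Ld,P} {Ld,F}> (n = 2)"`.
#' @seealso [parse_pattern_notation()] for the inverse.
#' @export
format_pattern_notation <- function(pattern, count = NULL) {
  format.behavior_pattern(pattern, count = count)
}

#' Parse a pattern from table notation
#'
#' Reads the `<{A,B} {C}>` dialect, optionally followed by a trailing
#' `(n = k)` count. Whitespace around codes, commas and braces is ignored.
#' Codes are validated against the ethogram.
#'
#' @param text A single pattern string.
#' @param ethogram Behaviour registry used to validate codes; set to `NULL`
#'   to skip code validation.
#' @return A list with components `pattern` (a [behavior_pattern()]) and
#'   `count` (integer, `NA` when no `(n = k)` suffix is present).
#' @examples
#' parse_pattern_notation("<{Ld,P} {Ld,P,F,P}> (n = 3)")
#' @export
parse_pattern_notation <- function(text, ethogram = load_default_ethogram()) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  count <- NA_integer_
  m <- regmatches(s, regexec("\\(\\s*n\\s*=\\s*(\\d+)\\s*\\)\\s*$", s))[[1]]
  if (length(m) == 2L) {
    count <- as.integer(m[2])
    s <- trimws(sub("\\(\\s*n\\s*=\\s*\\d+\\s*\\)\\s*$", "", s))
  }
  if (!grepl("^<.*>$", s)) {
    stop("malformed pattern (missing angle brackets): ", text, call. = FALSE)
  }
  body <- substr(s, 2L, nchar(s) - 1L)
  if (grepl("[<>]", body)) {
    stop("malformed pattern (nested angle brackets): ", text, call. = FALSE)
  }
  # tokenize braces strictly: elements are {..} groups, nothing outside them
  elements <- list()
  rest <- trimws(body)
  while (nzchar(rest)) {
    m <- regexec("^\\{([^{}]*)\\}", rest)[[1]]
    if (m[1] == -1L) {
      stop("malformed pattern (unbalanced or stray braces): ", text,
           call. = FALSE)
    }
    inner <- regmatches(rest, regexec("^\\{([^{}]*)\\}", rest))[[1]][2]
    codes <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    if (!length(codes)) {
      stop("malformed pattern (empty element): ", text, call. = FALSE)
    }
    elements[[length(elements) + 1L]] <- codes
    rest <- trimws(substr(rest, attr(m, "match.length")[1] + 1L, nchar(rest)))
  }
  if (!length(elements)) {
    stop("malformed pattern (no elements): ", text, call. = FALSE)
  }
  if (!is.null(ethogram)) {
    codes <- unique(unlist(elements))
    bad <- setdiff(codes, ethogram$acronym)
    if (length(bad)) {
      stop("unknown behaviour code(s) in pattern: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  list(pattern = behavior_pattern(elements), count = count)
}

#' Number of elements (steps) of a sequence or pattern
#'
#' The reporting convention counts *elements* (observation-window steps), not
#' items: a pattern of four elements totalling eight behaviour codes has size
#' 4. For a per-bird sequence, empty (event-free) windows are retained for
#' transaction-time alignment but do not count towards its size.
#'
#' @param x A `behavior_pattern`, `broiler_sequence`, or plain list of
#'   character vectors.
#' @return Integer number of non-empty elements.
#' @examples
#' sequence_size(behavior_pattern(list(c("P","F","P"), c("Ld","P"))))  # 2
#' @export
sequence_size <- function(x) {
  UseMethod("sequence_size")
}

#' @export
sequence_size.behavior_pattern <- function(x) {
  length(x)
}

#' @export
sequence_size.broiler_sequence <- function(x) {
  sum(vapply(x$elements, length, 1L) > 0L)
}

#' @export
sequence_size.list <- function(x) {
  sum(vapply(x, length, 1L) > 0L)
}

#' Total number of behaviour codes in a pattern
#'
#' The level variable of the mining engine (GSP convention), as opposed to
#' [sequence_size()] which counts elements (reporting convention).
#'
#' @param pattern A [behavior_pattern()].
#' @return Integer total item count.
#' @export
pattern_items <- function(pattern) {
  sum(vapply(unclass(pattern), length, 1L))
}

# ---- internal integer encoding ------------------------------------------
# Patterns and window sequences are encoded over an alphabet index; element
# boundaries are 0. Keys are the comma-joined encoding, used for hashing in
# candidate generation and dedup.

encode_pattern <- function(pattern, codes) {
  idx <- lapply(unclass(pattern), function(el) {
    i <- match(el, codes)
    if (anyNA(i)) stop("pattern code not in alphabet", call. = FALSE)
    i
  })
  out <- integer(0)
  for (k in seq_along(idx)) {
    if (k > 1L) out <- c(out, 0L)
    out <- c(out, idx[[k]])
  }
  out
}

decode_pattern <- function(enc, codes) {
  splits <- split(enc, cumsum(enc == 0L))
  elements <- lapply(splits, function(v) codes[v[v != 0L]])
  behavior_pattern(elements)
}

pattern_key <- function(enc) paste(enc, collapse = ",")
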