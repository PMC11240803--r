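#' Per-bird behaviour sequences and sequence databases
#'
#' A `broiler_sequence` holds one bird's chronologically ordered observation
#' windows ("transactions"); each window element is the ordered run of
#' behaviour codes recorded in that window. A `sequence_db` is an ordered
#' collection of such sequences keyed by a unique sequence id (SID), the
#' `<SID, s>` tuple model used by sequential pattern mining.
#'
#' @param sid Sequence id (one bird), a single string.
#' @param elements List of character vectors of behaviour codes, one per
#'   window, in transaction-time order. Empty vectors denote event-free
#'   windows and are retained for alignment.
#' @return `broiler_sequence()` returns an object of class
#'   `broiler_sequence`; `build_database()` an object of class `sequence_db`.
#' @export
broiler_sequence <- function(sid, elements) {
  stopifnot(is.character(sid), length(sid) == 1L, is.list(elements))
  elements <- lapply(elements, as.character)
  structure(list(sid = sid, elements = elements), class = "broiler_sequence")
}

#' @export
print.broiler_sequence <- function(x, ...) {
  nonempty <- Filter(length, x$elements)
  cat(sprintf("<%s> %d windows (%d with events): ", x$sid,
              length(x$elements), length(nonempty)))
  if (length(nonempty)) {
    cat(format(behavior_pattern(nonempty)), "\n")
  } else {
    cat("<>\n")
  }
  invisible(x)
}

#' Assemble a sequence database
#'
#' @param sequences A list of [broiler_sequence()] objects with unique SIDs.
#' @return A `sequence_db`: a list of sequences with attribute `n` (the
#'   number of sequences, the support denominator).
#' @examples
#' db <- build_database(list(
#'   broiler_sequence("broiler_1", list("E", "W", "D")),
#'   broiler_sequence("broiler_2", list("Ld", "P"))
#' ))
#' db_size(db)  # 2
#' @export
build_database <- function(sequences) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  ok <- vapply(sequences, inherits, TRUE, "broiler_sequence")
  if (!all(ok)) stop("all entries must be broiler_sequence objects", call. = FALSE)
  sids <- vapply(sequences, `[[`, "", "sid")
  if (anyDuplicated(sids)) {
    stop("duplicate SID(s): ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "), call. = FALSE)
  }
  structure(sequences, names = sids, n = length(sequences),
            class = "sequence_db")
}

#' Number of sequences in a database
#' @param db A `sequence_db`.
#' @return Integer count of sequences (the support denominator).
#' @export
db_size <- function(db) {
  stopifnot(inherits(db, "sequence_db"))
  attr(db, "n")
}

#' @export
print.sequence_db <- function(x, ...) {
  cat("Sequence database:", db_size(x), "sequences\n")
  for (s in x) print(s)
  invisible(x)
}

#' The two-bird worked-example database
#'
#' The small sequence database used throughout the documentation: bird 1
#' eats, walks, then drinks across three windows (size 3); bird 2 lies down
#' then preens (size 2).
#'
#' @return A `sequence_db` with two sequences.
#' @examples
#' db <- example_database()
#' sequence_size(db[["broiler_1"]])  # 3
#' @export
example_database <- function() {
  build_database(list(
    broiler_sequence("broiler_1", list("E", "W", "D")),
    broiler_sequence("broiler_2", list("Ld", "P"))
  ))
}

#' Convert annotated bouts into per-bird window sequences
#'
#' Applies the bout-to-transaction rules: a behaviour registers as an event
#' only when sustained for at least `min_bout_s` seconds (default 10 s);
#' shorter bouts are discarded. Bouts are assigned to the window containing
#' their onset and truncated at the window end, so a bout crossing a boundary
#' counts only if its within-window duration still reaches the floor.
#' Consecutive surviving bouts of the same behaviour merge into a single code
#' occurrence, so window elements never contain adjacent duplicate codes.
#'
#' @param bouts A data frame with columns `broiler_id`, `window_index`
#'   (0-based), `onset_s` (seconds from window start), `duration_s` and
#'   `behavior`. Extra columns (`condition`, `day`) are ignored here.
#' @param min_bout_s Minimum sustained duration for a bout to register
#'   (seconds).
#' @param window_s Window length in seconds.
#' @param n_windows Number of windows per bird; every returned sequence has
#'   exactly this many elements, empty ones retained.
#' @return A list of [broiler_sequence()] objects, one per bird, in order of
#'   first appearance in `bouts`.
#' @examples
#' b <- data.frame(broiler_id = "b1", window_index = 0,
#'                 onset_s = c(0, 120, 128), duration_s = c(120, 8, 60),
#'                 behavior = c("Ld", "P", "Ld"))
#' s <- bouts_to_windows(b, n_windows = 1)
#' s[[1]]$elements[[1]]  # "Ld": the 8 s preen is dropped, the runs merge
#' @export
bouts_to_windows <- function(bouts, min_bout_s = 10, window_s = 300,
                             n_windows = 14) {
  required <- c("broiler_id", "window_index", "onset_s", "duration_s",
                "behavior")
  missing <- setdiff(required, names(bouts))
  if (length(missing)) {
    stop("bout table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(bouts) && any(bouts$window_index >= n_windows)) {
    stop("window_index out of range (>= n_windows = ", n_windows, ")",
         call. = FALSE)
  }
  if (nrow(bouts) && any(bouts$window_index < 0)) {
    stop("window_index out of range (negative)", call. = FALSE)
  }
  if (nrow(bouts) && any(bouts$duration_s <= 0)) {
    stop("bout durations must be positive", call. = FALSE)
  }
  ids <- unique(as.character(bouts$broiler_id))
  lapply(ids, function(id) {
    rows <- bouts[as.character(bouts$broiler_id) == id, , drop = FALSE]
    elements <- vector("list", n_windows)
    for (w in seq_len(n_windows) - 1L) {
      wb <- rows[rows$window_index == w, , drop = FALSE]
      if (!nrow(wb)) {
        elements[[w + 1L]] <- character(0)
        next
      }
      wb <- wb[order(wb$onset_s), , drop = FALSE]
      ends <- wb$onset_s + wb$duration_s
      if (nrow(wb) > 1L && any(ends[-nrow(wb)] > wb$onset_s[-1L] + 1e-9)) {
        stop("overlapping bouts for ", id, " in window ", w, call. = FALSE)
      }
      # truncate at the window end; drop sub-floor bouts; merge same-code runs
      dur <- pmin(ends, window_s) - wb$onset_s
      keep <- dur >= min_bout_s - 1e-9 & wb$onset_s < window_s
      codes <- as.character(wb$behavior[keep])
      if (length(codes) > 1L) {
        codes <- codes[c(TRUE, codes[-1L] != codes[-length(codes)])]
      }
      elements[[w + 1L]] <- codes
    }
    broiler_sequence(id, elements)
  })
}

# ---- text round-trip formats --------------------------------------------

#' Read a bout annotation CSV
#'
#' Expected header: `broiler_id,condition,day,window_index,onset_s,duration_s,
#' behavior`. Values are validated against the ethogram; rows with unknown
#' codes or non-numeric fields are reported by row number. Durations below
#' the bout floor are accepted here — the floor rule belongs to
#' [bouts_to_windows()].
#'
#' @param path CSV file path.
#' @param ethogram Registry for code validation, or `NULL` to skip.
#' @return A data frame of bouts.
#' @export
read_bout_csv <- function(path, ethogram = load_default_ethogram()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("broiler_id", "condition", "day", "window_index", "onset_s",
                "duration_s", "behavior")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("bout CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$onset_s) | !is.finite(df$duration_s) |
                 df$duration_s <= 0 | !is.finite(df$window_index))
  if (!is.null(ethogram)) {
    bad <- union(bad, which(!(df$behavior %in% ethogram$acronym)))
  }
  if (length(bad)) {
    stop("invalid bout row(s): ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write bouts to CSV
#' @param bouts Bout data frame (see [read_bout_csv()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bout_csv <- function(bouts, path) {
  utils::write.csv(bouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a sequence database as text
#'
#' One line per transaction: tab-separated SID, 1-based transaction index and
#' comma-joined behaviour codes (empty for event-free windows), mirroring the
#' `<SID, s>` tabular layout. The round trip `read_db_text(write_db_text(db))`
#' reproduces `db` exactly.
#'
#' @param db A `sequence_db`.
#' @param path File path.
#' @return `write_db_text()` returns `path` invisibly; `read_db_text()`
#'   returns a `sequence_db`.
#' @export
write_db_text <- function(db, path) {
  stopifnot(inherits(db, "sequence_db"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in db) {
    for (k in seq_along(s$elements)) {
      writeLines(paste(s$sid, k, paste(s$elements[[k]], collapse = ","),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_db_text
#' @export
read_db_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed database line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sid <- vapply(parts, `[[`, "", 1L)
  tix <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tix)) {
    stop("non-integer transaction index at line(s): ",
         paste(which(is.na(tix)), collapse = ", "), call. = FALSE)
  }
  items <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", "")
  seqs <- lapply(unique(sid), function(id) {
    sel <- sid == id
    ord <- order(tix[sel])
    elements <- lapply(items[sel][ord], function(s) {
      if (!nzchar(s)) character(0) else trimws(strsplit(s, ",")[[1]])
    })
    broiler_sequence(id, elements)
  })
  build_database(seqs)
}
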