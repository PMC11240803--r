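#' Containment of a pattern element in an observation window
#'
#' An element matches a window when its codes embed into the window's code
#' run as an order-preserving, multiplicity-respecting subsequence; gaps are
#' allowed, so `P,F,P` matches a window recording `P,F,F,P`. Co-occurrence
#' within a single window is required for every code of one element.
#'
#' @param element Character vector of behaviour codes (a pattern element).
#' @param window Character vector of behaviour codes (one window's events).
#' @return `TRUE` or `FALSE`.
#' @examples
#' element_contained(c("Ld","P"), c("Ld","P","F","P"))  # TRUE
#' element_contained(c("E","W"), "E")                   # FALSE
#' @export
element_contained <- function(element, window) {
  np <- length(element)
  if (np == 0L) return(TRUE)
  if (length(window) < np) return(FALSE)
  i <- 1L
  for (code in window) {
    if (code == element[i]) {
      i <- i + 1L
      if (i > np) return(TRUE)
    }
  }
  FALSE
}

#' Containment of a pattern in a bird's sequence
#'
#' A sequence contains a pattern when the pattern's elements map to strictly
#' increasing windows of the sequence (one window per element, no reuse) with
#' [element_contained()] holding at each mapped window. Intervening windows
#' and intervening events are allowed.
#'
#' The greedy earliest-window embedding used here is exact: element matches
#' are independent across windows, so matching each element as early as
#' possible leaves the largest suffix for the remainder.
#'
#' @param seq A [broiler_sequence()] or plain list of character vectors.
#' @param pattern A [behavior_pattern()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' db <- example_database()
#' sequence_contains(db[["broiler_1"]],
#'                   behavior_pattern(list("E", "D")))  # TRUE, W may intervene
#' @export
sequence_contains <- function(seq, pattern) {
  elements <- if (inherits(seq, "broiler_sequence")) seq$elements else seq
  w <- 1L
  nw <- length(elements)
  for (el in unclass(pattern)) {
    repeat {
      if (w > nw) return(FALSE)
      if (element_contained(el, elements[[w]])) break
      w <- w + 1L
    }
    w <- w + 1L
  }
  TRUE
}

#' Support of a pattern in a sequence database
#'
#' Support is the fraction of database sequences (birds) that contain the
#' pattern; a bird counts once no matter how many embeddings exist. Reported
#' supports are therefore always integer multiples of `1 / db_size(db)`.
#'
#' @param pattern A [behavior_pattern()].
#' @param db A `sequence_db` with at least one sequence.
#' @return A list with components `pattern`, `support_count` (number of SIDs
#'   containing the pattern) and `support` (fraction in `[0, 1]`).
#' @examples
#' pattern_support(behavior_pattern(list("E", "D")), example_database())
#' @export
pattern_support <- function(pattern, db) {
  stopifnot(inherits(db, "sequence_db"))
  if (db_size(db) < 1L) stop("empty sequence database", call. = FALSE)
  cnt <- sum(vapply(db, sequence_contains, TRUE, pattern = pattern))
  list(pattern = pattern, support_count = as.integer(cnt),
       support = cnt / db_size(db))
}

# ---- encoded-pattern manipulation for the level-wise engine -------------

enc_items <- function(enc) sum(enc != 0L)
enc_size <- function(enc) sum(enc == 0L) + 1L

enc_drop_first <- function(enc) {
  enc <- enc[-1L]
  if (length(enc) && enc[1L] == 0L) enc <- enc[-1L]
  enc
}

enc_drop_last <- function(enc) {
  enc <- enc[-length(enc)]
  if (length(enc) && enc[length(enc)] == 0L) enc <- enc[-length(enc)]
  enc
}

# Delete the item at position p (an index into enc holding a non-zero code).
# Returns NULL when the deletion leaves a pattern outside the mined language
# (adjacent duplicate codes within an element); such subpatterns are never
# candidates, so their absence from the frequent set carries no information.
enc_delete_item <- function(enc, p) {
  n <- length(enc)
  left_sep <- p == 1L || enc[p - 1L] == 0L
  right_sep <- p == n || enc[p + 1L] == 0L
  if (left_sep && right_sep) {
    # singleton element: drop the element and one adjoining separator
    if (p < n) enc[-c(p, p + 1L)] else if (p > 1L) enc[-c(p - 1L, p)] else integer(0)
  } else if (!left_sep && !right_sep) {
    if (enc[p - 1L] == enc[p + 1L]) NULL else enc[-p]
  } else {
    enc[-p]
  }
}

canonical_enc_order <- function(encs) {
  if (!length(encs)) return(integer(0))
  items <- vapply(encs, enc_items, 1L)
  sizes <- vapply(encs, enc_size, 1L)
  keys <- vapply(encs, function(e) paste(sprintf("%02d", e), collapse = ""), "")
  order(items, sizes, keys)
}

#' GSP candidate generation (join + Apriori prune)
#'
#' Grows candidate patterns with `k + 1` behaviour codes from the frequent
#' patterns with `k` codes. Two seeds join when dropping the first code of
#' the first equals dropping the last code of the second; the joined
#' candidate appends the second seed's last code either merged into the
#' final element or as a new element, mirroring the second seed's structure.
#' For `k = 1` every ordered combination of the two codes is produced.
#' Candidates are then Apriori-pruned: a candidate survives only if every
#' single-code-deletion subpattern that stays inside the mined pattern
#' language (no adjacent duplicate codes within an element) is itself
#' frequent. Candidates never contain adjacent duplicate codes within an
#' element; window elements never do either (same-code runs merge at build
#' time), and such patterns are excluded from the search space by design.
#'
#' @param frequent_k A list of [behavior_pattern()] objects, all with the
#'   same total code count `k`.
#' @param ethogram Registry fixing the code alphabet and canonical order.
#' @return A list of candidate [behavior_pattern()]s in canonical order.
#' @examples
#' f1 <- list(behavior_pattern(list("Ld")), behavior_pattern(list("P")))
#' length(generate_candidates(f1))  # 6
#' @export
generate_candidates <- function(frequent_k, ethogram = load_default_ethogram()) {
  codes <- ethogram$acronym
  encs <- lapply(frequent_k, encode_pattern, codes = codes)
  cands <- generate_candidates_enc(encs)
  lapply(cands[canonical_enc_order(cands)], decode_pattern, codes = codes)
}

generate_candidates_enc <- function(encs) {
  if (!length(encs)) return(list())
  ks <- vapply(encs, enc_items, 1L)
  k <- ks[1L]
  if (any(ks != k)) {
    stop("candidate generation requires seeds of identical item count",
         call. = FALSE)
  }
  out <- new.env(parent = emptyenv())
  add <- function(enc) assign(pattern_key(enc), enc, envir = out)
  if (k == 1L) {
    items <- vapply(encs, `[[`, 0L, 1L)
    for (a in items) {
      for (b in items) {
        add(c(a, 0L, b))          # two one-code elements
        if (a != b) add(c(a, b))  # one two-code element
      }
    }
  } else {
    by_dropped_last <- new.env(parent = emptyenv())
    for (i in seq_along(encs)) {
      key <- pattern_key(enc_drop_last(encs[[i]]))
      assign(key, c(get0(key, envir = by_dropped_last, ifnotfound = integer(0)), i),
             envir = by_dropped_last)
    }
    for (s1 in encs) {
      key <- pattern_key(enc_drop_first(s1))
      for (j in get0(key, envir = by_dropped_last, ifnotfound = integer(0))) {
        s2 <- encs[[j]]
        last <- s2[length(s2)]
        last_alone <- length(s2) >= 2L && s2[length(s2) - 1L] == 0L
        if (last_alone) {
          add(c(s1, 0L, last))
        } else if (s1[length(s1)] != last) {
          add(c(s1, last))
        }
      }
    }
  }
  cands <- as.list(out)
  # Apriori prune against the seed set
  seed_keys <- new.env(parent = emptyenv())
  for (e in encs) assign(pattern_key(e), TRUE, envir = seed_keys)
  keep <- vapply(cands, function(cand) {
    for (p in which(cand != 0L)) {
      sub <- enc_delete_item(cand, p)
      if (is.null(sub)) next
      if (!isTRUE(get0(pattern_key(sub), envir = seed_keys, ifnotfound = FALSE))) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  unname(cands[keep])
}

# shared result assembly
build_pattern_frame <- function(encs, counts, n, codes) {
  ord <- canonical_enc_order(encs)
  encs <- encs[ord]
  counts <- counts[ord]
  patterns <- lapply(encs, decode_pattern, codes = codes)
  df <- data.frame(
    notation = vapply(patterns, format_pattern_notation, ""),
    support_count = as.integer(counts),
    support = counts / n,
    item_count = vapply(encs, enc_items, 1L),
    size = vapply(encs, enc_size, 1L),
    stringsAsFactors = FALSE
  )
  df$pattern <- patterns
  # keep the integer encodings (and their alphabet) for downstream
  # subpattern work, avoiding re-encoding of large result sets
  attr(df, "enc") <- encs
  attr(df, "enc_alphabet") <- codes
  class(df) <- c("frequent_patterns", "data.frame")
  df
}

db_alphabet <- function(db, codes) {
  used <- unique(unlist(lapply(db, `[[`, "elements"), use.names = FALSE))
  unknown <- setdiff(used, codes)
  if (length(unknown)) {
    stop("database contains codes outside the ethogram: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  codes[codes %in% used]
}

encode_db <- function(db, alphabet) {
  lapply(db, function(s) lapply(s$elements, function(el) match(el, alphabet)))
}

support_threshold_count <- function(minsup, n) {
  if (!is.numeric(minsup) || length(minsup) != 1L || is.na(minsup) ||
      minsup <= 0 || minsup > 1) {
    stop("minsup must lie in (0, 1]", call. = FALSE)
  }
  # closed comparison support >= minsup, robust to floating-point thresholds
  as.integer(ceiling(minsup * n - 1e-9))
}

#' Mine frequent sequential patterns (level-wise GSP)
#'
#' Level-wise mining: the first pass counts the support of every single
#' behaviour code; each subsequent pass joins the frequent patterns of the
#' previous level into candidates one code longer ([generate_candidates()]),
#' counts candidate supports in one scan, and keeps those meeting `minsup`
#' (closed comparison, `support >= minsup`). Mining stops when a pass yields
#' no frequent pattern or no candidate. The result is complete — identical
#' to exhaustive enumeration ([brute_force_mine()]) over the pattern
#' language — and deterministically ordered (total code count, then element
#' count, then lexicographic in canonical ethogram code order).
#'
#' @param db A `sequence_db`.
#' @param minsup Minimum support fraction in `(0, 1]`.
#' @param ethogram Registry fixing the alphabet and canonical order.
#' @return A `frequent_patterns` data frame with columns `notation`,
#'   `support_count`, `support`, `item_count`, `size` and a list column
#'   `pattern`.
#' @examples
#' mine_gsp(example_database(), minsup = 0.5)
#' @export
mine_gsp <- function(db, minsup, ethogram = load_default_ethogram()) {
  stopifnot(inherits(db, "sequence_db"))
  n <- db_size(db)
  if (n < 1L) stop("empty sequence database", call. = FALSE)
  min_count <- support_threshold_count(minsup, n)
  alphabet <- db_alphabet(db, ethogram$acronym)
  all_encs <- list()
  all_counts <- integer(0)
  if (length(alphabet)) {
    db_enc <- encode_db(db, alphabet)
    level <- lapply(seq_along(alphabet), function(i) i)
    counts <- count_supports_cpp(db_enc, level)
    keep <- counts >= min_count
    level <- level[keep]
    counts <- counts[keep]
    while (length(level)) {
      all_encs <- c(all_encs, level)
      all_counts <- c(all_counts, counts)
      cands <- join_prune_cpp(level)
      if (!length(cands)) break
      counts <- count_supports_cpp(db_enc, cands)
      keep <- counts >= min_count
      level <- cands[keep]
      counts <- counts[keep]
    }
  }
  build_pattern_frame(all_encs, all_counts, n, alphabet)
}

#' Exhaustive brute-force mining oracle
#'
#' Enumerates the complete pattern language over the codes present in the
#' database — every ordered element composition without adjacent duplicate
#' codes inside an element — up to `max_items` total codes, computes every
#' support by direct containment testing ([sequence_contains()], a pure-R
#' path independent of the mining engine's counting kernel), and filters by
#' `minsup`. Intended for verification on small inputs (guidance: at most 12
#' sequences, 6 windows each, an alphabet of 6 codes and `max_items <= 5`);
#' the enumeration size is checked against `max_enum` up front.
#'
#' @param db A `sequence_db`.
#' @param minsup Minimum support fraction in `(0, 1]`.
#' @param max_items Maximum total code count per enumerated pattern.
#' @param ethogram Registry fixing the alphabet and canonical order.
#' @param max_enum Enumeration budget; exceeding it is an error.
#' @return A `frequent_patterns` data frame in the same contract and
#'   ordering as [mine_gsp()].
#' @export
brute_force_mine <- function(db, minsup, max_items = 4L,
                             ethogram = load_default_ethogram(),
                             max_enum = 2e5) {
  stopifnot(inherits(db, "sequence_db"))
  n <- db_size(db)
  if (n < 1L) stop("empty sequence database", call. = FALSE)
  min_count <- support_threshold_count(minsup, n)
  alphabet <- db_alphabet(db, ethogram$acronym)
  a <- length(alphabet)
  if (a) {
    total <- sum(a * (2 * a - 1)^(seq_len(max_items) - 1))
    if (total > max_enum) {
      stop("enumeration budget exceeded (", format(total, big.mark = ","),
           " patterns > max_enum = ", format(max_enum, big.mark = ","), ")",
           call. = FALSE)
    }
  }
  elems_by_seq <- lapply(db, `[[`, "elements")
  hits <- list()
  counts <- integer(0)
  visit <- function(enc) {
    pat <- decode_pattern(enc, alphabet)
    cnt <- sum(vapply(elems_by_seq, sequence_contains, TRUE, pattern = pat))
    if (cnt >= min_count) {
      hits[[length(hits) + 1L]] <<- enc
      counts[[length(counts) + 1L]] <<- cnt
    }
    if (enc_items(enc) < max_items) {
      last <- enc[length(enc)]
      for (cc in seq_len(a)) {
        if (cc != last) visit(c(enc, cc))   # merged into final element
        visit(c(enc, 0L, cc))               # new element
      }
    }
  }
  for (cc in seq_len(a)) visit(cc)
  build_pattern_frame(hits, counts, n, alphabet)
}

#' @export
print.frequent_patterns <- function(x, max = 20L, ...) {
  cat(nrow(x), "frequent pattern(s)\n")
  show <- utils::head(x, max)
  if (nrow(show)) {
    print.data.frame(show[, c("notation", "support_count", "support",
                              "item_count", "size")], row.names = FALSE)
    if (nrow(x) > max) cat("... and", nrow(x) - max, "more\n")
  }
  invisible(x)
}

#' Export mined patterns as JSON lines
#'
#' One JSON object per pattern with fields `pattern` (table notation),
#' `support_count`, `support`, `item_count` and `size`.
#'
#' @param patterns A `frequent_patterns` frame from [mine_gsp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patterns_jsonl <- function(patterns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(patterns))) {
    writeLines(jsonlite::toJSON(list(
      pattern = patterns$notation[i],
      support_count = patterns$support_count[i],
      support = patterns$support[i],
      item_count = patterns$item_count[i],
      size = patterns$size[i]
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
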