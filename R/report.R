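#' Is one pattern a subpattern of another?
#'
#' Subpattern means containment under the mining semantics, treating the
#' larger pattern's elements as windows: `<{Ld}>` is a subpattern of
#' `<{Ld,P}>`, and `<{Ld,F}>` of `<{Ld,F} {Ld,P}>`.
#'
#' @param p,q [behavior_pattern()] objects.
#' @return `TRUE` when `p` embeds into `q` (including `p` equal to `q`).
#' @export
pattern_subpattern <- function(p, q) {
  sequence_contains(unclass(q), p)
}

#' Minimum-support threshold sweep with novelty reporting
#'
#' Runs the miner over a strictly decreasing grid of minimum-support levels
#' and reports, at each level, only what is new: the maximal frequent
#' patterns at that level (no frequent proper superpattern at the same
#' level), minus any pattern that is identical to or a subpattern of a
#' pattern reported at a higher level. Levels at which nothing is frequent,
#' or nothing new remains, report an empty set. Mining happens once at the
#' lowest level; higher levels are exact subsets by support.
#'
#' @param db A `sequence_db`.
#' @param levels Strictly decreasing support levels in `(0, 1]`; default
#'   `1.0, 0.9, ..., 0.2`.
#' @param condition_id Label attached to the report.
#' @param ethogram Registry fixing alphabet and canonical order.
#' @return A `sweep_report`: list with `condition_id` and `levels`, the
#'   latter a list of per-level records `minsup`, `levels` (the grid points
#'   the row covers, here one each), `label`, `reported` (a
#'   `frequent_patterns` frame) and `maximal_notations` (the level-local
#'   maximal set before cross-level suppression, used for display
#'   collapsing).
#' @examples
#' sweep_report <- sweep_minsup(example_database(), levels = c(0.5),
#'                              condition_id = "toy")
#' @export
sweep_minsup <- function(db, levels = seq(1.0, 0.2, by = -0.1),
                         condition_id = "unlabelled",
                         ethogram = load_default_ethogram()) {
  if (!is.numeric(levels) || !length(levels) || any(levels <= 0 | levels > 1)) {
    stop("levels must lie in (0, 1]", call. = FALSE)
  }
  if (length(levels) > 1L && any(diff(levels) >= -1e-12)) {
    stop("levels must be strictly decreasing", call. = FALSE)
  }
  mined <- mine_gsp(db, minsup = min(levels), ethogram = ethogram)
  n <- db_size(db)
  encs <- attr(mined, "enc")
  if (is.null(encs)) {
    encs <- lapply(mined$pattern, encode_pattern, codes = ethogram$acronym)
  }
  # element-list form is only needed for the (few) maximal patterns
  as_elements <- function(i) {
    e <- encs[[i]]
    idx <- split(e, cumsum(e == 0L))
    lapply(idx, function(v) v[v != 0L])
  }
  reported_sofar <- list()  # patterns reported at higher levels
  out_levels <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    m <- levels[li]
    freq_idx <- which(mined$support_count >= support_threshold_count(m, n))
    maximal_idx <- integer(0)
    if (length(freq_idx)) {
      flags <- maximal_flags_cpp(encs[freq_idx])
      maximal_idx <- freq_idx[flags]
    }
    maximal_notations <- mined$notation[maximal_idx]
    maximal_els <- lapply(maximal_idx, as_elements)
    new_flag <- vapply(seq_along(maximal_idx), function(ii) {
      for (r in reported_sofar) {
        if (contained_enc(r, maximal_els[[ii]])) return(FALSE)
      }
      TRUE
    }, TRUE)
    new_idx <- maximal_idx[new_flag]
    reported <- mined[match(new_idx, seq_len(nrow(mined))), , drop = FALSE]
    rownames(reported) <- NULL
    reported_sofar <- c(reported_sofar, maximal_els[new_flag])
    out_levels[[li]] <- list(
      minsup = m, levels = m, label = format_level(m),
      reported = reported, maximal_notations = maximal_notations
    )
  }
  structure(list(condition_id = condition_id, levels = out_levels),
            class = "sweep_report")
}

# containment of pattern p (list of int vectors) within q's elements treated
# as windows; both in encoded element-list form
contained_enc <- function(q_elements, p_elements) {
  w <- 1L
  nw <- length(q_elements)
  for (el in p_elements) {
    repeat {
      if (w > nw) return(FALSE)
      if (int_elem_in(el, q_elements[[w]])) break
      w <- w + 1L
    }
    w <- w + 1L
  }
  TRUE
}

int_elem_in <- function(el, win) {
  np <- length(el)
  if (np == 0L) return(TRUE)
  if (length(win) < np) return(FALSE)
  i <- 1L
  for (v in win) {
    if (v == el[i]) {
      i <- i + 1L
      if (i > np) return(TRUE)
    }
  }
  FALSE
}

format_level <- function(m) trimws(format(round(m, 3), nsmall = 1))

#' @export
print.sweep_report <- function(x, ...) {
  cat("Support sweep for condition:", x$condition_id, "\n")
  cat(format_sweep_text(x), sep = "\n")
  invisible(x)
}

#' Render a sweep report as a threshold table
#'
#' Produces the three-column layout `MinSupport | Sequence Number |
#' Sequence`. With `collapse = TRUE`, consecutive levels whose level-local
#' maximal sets are identical are merged into a single row (the upper level
#' carries the report); rows where nothing is frequent print `None`.
#'
#' @param report A `sweep_report`.
#' @param collapse Merge adjacent equivalent levels into one labelled row.
#' @return Character vector of table lines.
#' @export
format_sweep_text <- function(report, collapse = TRUE) {
  rows <- report$levels
  if (collapse && length(rows) > 1L) {
    groups <- list()
    cur <- rows[[1L]]
    for (r in rows[-1L]) {
      same <- !is.null(cur$maximal_notations) &&
        !is.null(r$maximal_notations) &&
        identical(sort(cur$maximal_notations), sort(r$maximal_notations))
      if (same) {
        cur$levels <- c(cur$levels, r$levels)
        cur$reported <- rbind(cur$reported, r$reported)
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- r
      }
    }
    groups[[length(groups) + 1L]] <- cur
    rows <- groups
  }
  header <- "MinSupport\tSequence Number\tSequence"
  lines <- vapply(rows, function(r) {
    label <- level_set_label(r$levels)
    if (!nrow(r$reported)) {
      paste(label, "None", "", sep = "\t")
    } else {
      tal <- table(r$reported$size)
      num <- paste(sprintf("%d size %s", as.integer(tal), names(tal)),
                   collapse = ", ")
      pats <- paste(vapply(seq_len(nrow(r$reported)), function(i) {
        format_pattern_notation(r$reported$pattern[[i]],
                                count = r$reported$support_count[i])
      }, ""), collapse = "; ")
      paste(label, num, pats, sep = "\t")
    }
  }, "")
  c(header, lines)
}

level_set_label <- function(levels) {
  levels <- sort(unique(levels), decreasing = TRUE)
  if (length(levels) == 1L) return(format_level(levels))
  consecutive <- all(abs(diff(levels) + 0.1) < 1e-9)
  if (consecutive && length(levels) > 3L) {
    paste(format_level(levels[1L]), "to", format_level(levels[length(levels)]))
  } else if (length(levels) == 2L) {
    paste(format_level(levels[1L]), "and", format_level(levels[2L]))
  } else {
    paste0(paste(format_level(levels[-length(levels)]), collapse = ", "),
           " and ", format_level(levels[length(levels)]))
  }
}

#' Per-level size composition of a sweep report
#'
#' @param report A `sweep_report`.
#' @return A data frame with columns `minsup`, `size` and `count`; one row
#'   per (level, size) with at least one reported pattern. Counts at each
#'   level sum to the number of patterns reported there.
#' @export
tally_sizes <- function(report) {
  rows <- lapply(report$levels, function(r) {
    if (!nrow(r$reported)) return(NULL)
    tal <- table(r$reported$size)
    data.frame(minsup = r$minsup, size = as.integer(names(tal)),
               count = as.integer(tal))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(minsup = numeric(0), size = integer(0),
                      count = integer(0))
  }
  out
}

#' Total number of distinct patterns reported across a sweep
#'
#' @param report A `sweep_report`.
#' @return Integer count of distinct reported patterns over all levels.
#' @export
total_patterns <- function(report) {
  notations <- unlist(lapply(report$levels, function(r) r$reported$notation))
  length(unique(notations))
}

#' Behaviour coverage of sweep reports
#'
#' Partitions the ethogram into behaviours that appear in at least one
#' reported pattern and those absent from every reported pattern.
#'
#' @param reports A `sweep_report` or list of them.
#' @param ethogram Behaviour registry.
#' @return List with character vectors `used` and `absent`, both in
#'   canonical ethogram order.
#' @export
behavior_coverage <- function(reports, ethogram = load_default_ethogram()) {
  if (inherits(reports, "sweep_report")) reports <- list(reports)
  used <- unique(unlist(lapply(reports, function(rep) {
    unlist(lapply(rep$levels, function(r) unlist(r$reported$pattern)))
  })))
  codes <- ethogram$acronym
  list(used = codes[codes %in% used], absent = codes[!(codes %in% used)])
}

#' Maximum reported pattern size across sweep reports
#'
#' @param reports A `sweep_report` or list of them.
#' @return Integer maximum element count over all reported patterns; 0 when
#'   nothing is reported.
#' @export
max_reported_size <- function(reports) {
  if (inherits(reports, "sweep_report")) reports <- list(reports)
  sizes <- unlist(lapply(reports, function(rep) {
    unlist(lapply(rep$levels, function(r) r$reported$size))
  }))
  if (!length(sizes)) 0L else max(sizes)
}

#' Read a packaged condition pattern table
#'
#' The package ships transcriptions of observed broiler pattern tables for
#' the four housing-by-temperature conditions as tab-separated text under
#' `inst/extdata` (files `patterns_<condition>.tsv`). Each data line holds a
#' verbatim MinSupport row label (for example `1.0, 0.9 and 0.8` or
#' `1.0 to 0.5`) and the reported patterns in table notation separated by
#' semicolons, or `None`. A `# condition:` comment records the condition id.
#'
#' @param path Path to a fixture file, or the bare condition name
#'   (`thermoneutral_plain`, `thermoneutral_enriched`, `heat_plain`,
#'   `heat_enriched`) to load the packaged copy.
#' @param ethogram Registry for code validation.
#' @return A `sweep_report` whose rows may cover several collapsed levels;
#'   `minsup` is the highest level of each row.
#' @examples
#' rep <- read_sweep_fixture("thermoneutral_plain")
#' total_patterns(rep)  # 27
#' @export
read_sweep_fixture <- function(path, ethogram = load_default_ethogram()) {
  if (!file.exists(path)) {
    candidate <- system.file("extdata", paste0("patterns_", path, ".tsv"),
                             package = "broilerseq")
    if (nzchar(candidate)) path <- candidate
  }
  if (!file.exists(path)) stop("fixture not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  condition_id <- sub("^#\\s*condition:\\s*", "",
                      grep("^#\\s*condition:", lines, value = TRUE)[1])
  if (is.na(condition_id)) condition_id <- basename(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    label <- trimws(parts[1])
    body <- if (length(parts) >= 2L) trimws(parts[2]) else ""
    levels <- parse_level_label(label)
    if (!nzchar(body) || identical(body, "None")) {
      reported <- empty_pattern_frame()
    } else {
      entries <- trimws(strsplit(body, ";", fixed = TRUE)[[1]])
      entries <- entries[nzchar(entries)]
      parsed <- lapply(entries, parse_pattern_notation, ethogram = ethogram)
      reported <- data.frame(
        notation = vapply(parsed, function(p) format_pattern_notation(p$pattern), ""),
        support_count = vapply(parsed, function(p) as.integer(p$count), 1L),
        support = NA_real_,
        item_count = vapply(parsed, function(p) pattern_items(p$pattern), 1L),
        size = vapply(parsed, function(p) sequence_size(p$pattern), 1L),
        stringsAsFactors = FALSE
      )
      reported$pattern <- lapply(parsed, `[[`, "pattern")
      class(reported) <- c("frequent_patterns", "data.frame")
    }
    list(minsup = max(levels), levels = levels, label = label,
         reported = reported, maximal_notations = NULL)
  })
  structure(list(condition_id = condition_id, levels = rows),
            class = "sweep_report")
}

parse_level_label <- function(label) {
  nums <- as.numeric(regmatches(label, gregexpr("[0-9]*\\.?[0-9]+", label))[[1]])
  if (!length(nums)) stop("unparseable level label: ", label, call. = FALSE)
  if (grepl("\\bto\\b", label) && length(nums) == 2L) {
    nums <- seq(nums[1], nums[2], by = -0.1)
  }
  round(nums, 10)
}

empty_pattern_frame <- function() {
  df <- data.frame(notation = character(0), support_count = integer(0),
                   support = numeric(0), item_count = integer(0),
                   size = integer(0), stringsAsFactors = FALSE)
  df$pattern <- list()
  class(df) <- c("frequent_patterns", "data.frame")
  df
}

#' Export a sweep report as JSON
#'
#' @param report A `sweep_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(report, path) {
  payload <- list(
    condition_id = report$condition_id,
    levels = lapply(report$levels, function(r) {
      list(minsup = r$minsup, label = r$label,
           reported = lapply(seq_len(nrow(r$reported)), function(i) {
             list(pattern = r$reported$notation[i],
                  support_count = r$reported$support_count[i],
                  size = r$reported$size[i])
           }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
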