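#' Condition presets for the flock simulator
#'
#' Each preset parameterises the semi-Markov behaviour generator for one
#' housing-by-temperature condition: a next-behaviour transition weight
#' matrix over the 13 codes (self-transitions zero, since same-code runs are
#' a single bout), per-code mean dwell times in seconds, and an
#' `activity_scale` factor. Dwell means are divided by `activity_scale`, so
#' smaller values mean longer bouts and fewer behavioural events — the
#' activity reduction characteristic of heat stress. The presets encode the
#' qualitative condition contrasts, not fitted magnitudes:
#'
#' * `Ex` (exploring enrichment) is allowed only in enriched presets;
#' * lying laterally (`Ll`), the heat-dissipation posture, has positive
#'   weight only under heat;
#' * the stretch-then-lie-laterally transition (`St` to `Ll`) is strongly
#'   elevated in the non-enriched heat preset, where that thermoregulatory
#'   motif is expected;
#' * heat presets have a lower `activity_scale` than thermoneutral ones.
#'
#' @param label One of `"thermoneutral_plain"`, `"thermoneutral_enriched"`,
#'   `"heat_plain"`, `"heat_enriched"`.
#' @return An object of class `condition_preset`: list with `label`,
#'   `enriched`, `allowed_codes`, `transition_weights` (13 x 13 matrix,
#'   rows = current code), `start_weights`, `dwell_mean_s` (named vector)
#'   and `activity_scale`.
#' @examples
#' p <- condition_preset("heat_plain")
#' p$transition_weights["St", "Ll"] > p$transition_weights["Ld", "Ll"]
#' @export
condition_preset <- function(label = c("thermoneutral_plain",
                                       "thermoneutral_enriched",
                                       "heat_plain", "heat_enriched")) {
  label <- match.arg(label)
  codes <- ethogram_codes()
  enriched <- grepl("enriched", label)
  heat <- grepl("heat", label)

  # baseline attractiveness of each behaviour as the *next* behaviour
  attract <- c(Ld = 3, P = 2.4, F = 2.2, W = 1.8, Db = 0.5, Wf = 0.5,
               Sf = 0.8, E = 1.6, D = 1.4, R = 0.5, St = 1, Ll = 0, Ex = 0)
  if (enriched) attract[["Ex"]] <- 1.4
  if (heat) {
    attract[["Ll"]] <- if (enriched) 1.4 else 2.2
    attract[["W"]] <- 1.2     # less locomotion in the heat
    attract[["R"]] <- 0.2
    attract[["F"]] <- 1.6
  }

  W <- matrix(rep(attract, each = length(codes)), nrow = length(codes),
              dimnames = list(codes, codes))
  # motif structure: feeding circuit and comfort/rest transitions
  boost <- function(from, to, f) W[from, to] <<- W[from, to] * f
  boost("Ld", "P", 2); boost("P", "F", 1.8); boost("F", "P", 1.8)
  boost("E", "W", 2); boost("W", "D", 1.8); boost("D", "W", 1.8)
  boost("W", "F", 1.8); boost("E", "F", 1.4)
  if (heat) {
    # stretch then lie laterally: the thermoregulatory signature, strongly
    # expressed only without enrichment
    boost("St", "Ll", if (enriched) 1 else 8)
    boost("P", "St", 1.8)
  }
  diag(W) <- 0
  W[, attract == 0] <- 0

  # resting postures dwell for minutes, active behaviours for tens of
  # seconds; event density per window therefore tracks how much of the
  # window is spent resting. Means are set so that mined pattern structure
  # matches observed flocks: a handful of behaviours recur per window, and
  # patterns shared across birds stay shallow (maximal sizes of a few
  # elements at a 20% support threshold).
  dwell <- c(Ld = 1600, P = 480, F = 450, W = 280, Db = 600, Wf = 200,
             Sf = 300, E = 540, D = 380, R = 200, St = 250, Ll = 1600,
             Ex = 450)

  structure(list(
    label = label,
    enriched = enriched,
    allowed_codes = codes[attract > 0],
    transition_weights = W,
    start_weights = attract,
    dwell_mean_s = dwell,
    activity_scale = if (heat) 0.45 else 1.0
  ), class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("Condition preset:", x$label, "\n")
  cat("  allowed codes: ", paste(x$allowed_codes, collapse = ", "), "\n")
  cat("  activity scale:", x$activity_scale, "\n")
  invisible(x)
}

#' The four-condition preset registry
#'
#' @return Named list of the four [condition_preset()]s.
#' @export
preset_registry <- function() {
  labels <- c("thermoneutral_plain", "thermoneutral_enriched",
              "heat_plain", "heat_enriched")
  stats::setNames(lapply(labels, condition_preset), labels)
}

#' Write / read the preset registry as YAML
#'
#' @param presets Named list of [condition_preset()]s.
#' @param path YAML file path.
#' @return `write_preset_yaml()` returns `path` invisibly;
#'   `read_preset_yaml()` returns the named preset list.
#' @export
write_preset_yaml <- function(presets = preset_registry(), path) {
  payload <- lapply(presets, function(p) {
    list(label = p$label, enriched = p$enriched,
         allowed_codes = p$allowed_codes,
         transition_weights = apply(p$transition_weights, 1, as.list,
                                    simplify = FALSE),
         start_weights = as.list(p$start_weights),
         dwell_mean_s = as.list(p$dwell_mean_s),
         activity_scale = p$activity_scale)
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @export
read_preset_yaml <- function(path) {
  payload <- yaml::read_yaml(path)
  lapply(payload, function(p) {
    codes <- names(p$start_weights)
    W <- do.call(rbind, lapply(p$transition_weights, function(r) unlist(r)))
    dimnames(W) <- list(names(p$transition_weights), codes)
    structure(list(
      label = p$label, enriched = p$enriched,
      allowed_codes = unlist(p$allowed_codes),
      transition_weights = W[codes, codes],
      start_weights = unlist(p$start_weights),
      dwell_mean_s = unlist(p$dwell_mean_s),
      activity_scale = p$activity_scale
    ), class = "condition_preset")
  })
}

#' Simulation configuration
#'
#' Defaults mirror the observation protocol the generator emulates: ten
#' birds per condition, fourteen five-minute windows per bird-day, and a
#' ten-second bout floor.
#'
#' @param preset A [condition_preset()] or its label.
#' @param n_broilers Number of birds.
#' @param n_windows Observation windows per bird.
#' @param window_s Window length, seconds.
#' @param min_bout_s Bout floor, seconds; also the generator's dwell floor so
#'   simulated bouts survive windowing by construction.
#' @param heterogeneity Gamma shape of per-bird behaviour preference
#'   multipliers; smaller values give more individual birds (the
#'   individual-rather-than-flock rhythm reported for poultry). Mean is 1,
#'   so condition-level structure is preserved.
#' @param window_heterogeneity Gamma shape of per-window preference
#'   multipliers, modelling short-term behavioural context: each window is
#'   dominated by a few behaviours (a resting spell, a feeding circuit)
#'   rather than sampling the whole repertoire uniformly.
#' @param seed Integer seed; same config and seed give identical bouts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = "thermoneutral_plain", n_broilers = 10L,
                       n_windows = 14L, window_s = 300, min_bout_s = 10,
                       heterogeneity = 0.5, window_heterogeneity = 0.25,
                       seed = 1L) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"),
            n_broilers >= 1L, window_s >= min_bout_s)
  structure(list(preset = preset, n_broilers = as.integer(n_broilers),
                 n_windows = as.integer(n_windows), window_s = window_s,
                 min_bout_s = min_bout_s, heterogeneity = heterogeneity,
                 window_heterogeneity = window_heterogeneity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_weighted <- function(w) {
  tot <- sum(w)
  if (tot <= 0) stop("unnormalizable transition row in preset", call. = FALSE)
  sample.int(length(w), 1L, prob = w / tot)
}

#' Simulate bout streams for a flock
#'
#' Seeded semi-Markov generator. Each bird receives individual behaviour
#' preference multipliers (Gamma with mean 1), and each bird-window an
#' additional preference draw modelling short-term behavioural context, so
#' windows are dominated by a few behaviours as in observed recordings.
#' Within a window the bird performs a walk: the next behaviour is drawn
#' from the current row of the preset's transition weight matrix (times the
#' bird and window preferences), and the bout dwell is exponential with a
#' floor at `min_bout_s` and mean `dwell_mean_s / activity_scale`. The last
#' bout of a window is truncated at the window end (truncations shorter
#' than the floor are later discarded by [bouts_to_windows()]). Identical
#' configs and seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A bout data frame with columns `broiler_id`, `condition`, `day`,
#'   `window_index`, `onset_s`, `duration_s`, `behavior`.
#' @examples
#' bouts <- simulate_flock(sim_config("heat_plain", seed = 7))
#' any(bouts$behavior == "Ex")  # FALSE: exploring needs enrichment
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$preset
  codes <- colnames(p$transition_weights)
  allowed <- codes %in% p$allowed_codes
  if (!any(allowed)) stop("preset allows no behaviours", call. = FALSE)
  bad_rows <- rowSums(p$transition_weights[allowed, allowed, drop = FALSE]) <= 0
  if (any(bad_rows)) {
    stop("unnormalizable transition row(s): ",
         paste(p$allowed_codes[bad_rows], collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  day <- if (grepl("heat", p$label)) 22L else 21L
  acc <- list()
  for (b in seq_len(config$n_broilers)) {
    id <- sprintf("broiler_%02d", b)
    pref <- stats::rgamma(length(codes), shape = config$heterogeneity,
                          rate = config$heterogeneity)
    pref[!allowed] <- 0
    for (w in seq_len(config$n_windows) - 1L) {
      wpref <- pref * stats::rgamma(length(codes),
                                    shape = config$window_heterogeneity,
                                    rate = config$window_heterogeneity)
      start_w <- p$start_weights * wpref
      t <- 0
      cur <- 0L
      beh <- integer(0); ons <- numeric(0); dur <- numeric(0)
      while (t < config$window_s - 1e-9) {
        trans_w <- if (cur == 0L) start_w else p$transition_weights[cur, ] * wpref
        nxt <- draw_weighted(trans_w)
        mean_extra <- max(p$dwell_mean_s[nxt] / p$activity_scale -
                            config$min_bout_s, 0.5)
        dwell <- config$min_bout_s + stats::rexp(1L, rate = 1 / mean_extra)
        beh <- c(beh, nxt)
        ons <- c(ons, t)
        dur <- c(dur, min(dwell, config$window_s - t))
        t <- t + dwell
        cur <- nxt
      }
      acc[[length(acc) + 1L]] <- data.frame(
        broiler_id = id, condition = p$label, day = day, window_index = w,
        onset_s = ons, duration_s = dur, behavior = codes[beh],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Plant a pattern into a simulated bout stream
#'
#' Splices a pattern into a chosen fraction of birds so that mined support
#' can be checked against a known ground truth. For each carrier, the
#' pattern's elements are inserted at the start of distinct, increasing,
#' randomly chosen windows as bouts of exactly the bout floor; pre-existing
#' bouts in those windows are displaced later in time and truncated at the
#' window end (sub-floor remnants are discarded by windowing).
#'
#' @param bouts A bout data frame from [simulate_flock()].
#' @param pattern A [behavior_pattern()] to plant.
#' @param carrier_fraction Fraction of birds to receive the pattern, in
#'   `(0, 1]`; `ceiling(carrier_fraction * n_broilers)` carriers are chosen.
#' @param config The [sim_config()] used to generate `bouts`.
#' @param seed Seed for carrier and window selection.
#' @return The modified bout data frame.
#' @examples
#' cfg <- sim_config("thermoneutral_plain", seed = 3)
#' bouts <- plant_pattern(simulate_flock(cfg),
#'                        behavior_pattern(list(c("St", "Ll"))),
#'                        carrier_fraction = 0.4, config = cfg, seed = 99)
#' @export
plant_pattern <- function(bouts, pattern, carrier_fraction, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"),
            carrier_fraction > 0, carrier_fraction <= 1)
  pattern <- behavior_pattern(unclass(pattern))
  if (length(pattern) > config$n_windows) {
    stop("capacity error: pattern has more elements than windows",
         call. = FALSE)
  }
  elem_len <- vapply(unclass(pattern), length, 1L)
  if (any(elem_len * config$min_bout_s > config$window_s)) {
    stop("capacity error: element does not fit within a window",
         call. = FALSE)
  }
  ids <- unique(bouts$broiler_id)
  k <- ceiling(carrier_fraction * length(ids))
  set.seed(seed)
  carriers <- sample(ids, k)
  out <- bouts
  for (id in carriers) {
    wins <- sort(sample.int(config$n_windows, length(pattern))) - 1L
    for (e in seq_along(wins)) {
      el <- unclass(pattern)[[e]]
      span <- length(el) * config$min_bout_s
      sel <- out$broiler_id == id & out$window_index == wins[e]
      # displace existing bouts past the planted block
      out$onset_s[sel] <- out$onset_s[sel] + span
      ends <- pmin(out$onset_s[sel] + out$duration_s[sel], config$window_s)
      out$duration_s[sel] <- ends - out$onset_s[sel]
      drop <- sel & (out$onset_s >= config$window_s - 1e-9 |
                       out$duration_s <= 1e-9)
      out <- out[!drop, , drop = FALSE]
      planted <- data.frame(
        broiler_id = id,
        condition = if (nrow(bouts)) bouts$condition[1] else config$preset$label,
        day = if (nrow(bouts)) bouts$day[1] else NA_integer_,
        window_index = wins[e],
        onset_s = (seq_along(el) - 1L) * config$min_bout_s,
        duration_s = config$min_bout_s,
        behavior = el,
        stringsAsFactors = FALSE
      )
      out <- rbind(out, planted)
    }
  }
  out <- out[order(out$broiler_id, out$window_index, out$onset_s), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call pipeline: simulate, window and assemble a database
#'
#' @param config A [sim_config()].
#' @return A `sequence_db` for the simulated flock.
#' @export
simulate_database <- function(config) {
  bouts <- simulate_flock(config)
  build_database(bouts_to_windows(bouts, min_bout_s = config$min_bout_s,
                                  window_s = config$window_s,
                                  n_windows = config$n_windows))
}
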