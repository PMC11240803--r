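make_shared_motif_db <- function() {
  # ten birds all share one Ld,P window; deeper structure only in a minority
  seqs <- lapply(1:10, function(i) {
    extra <- if (i <= 3) list(c("E", "W")) else list(character(0))
    broiler_sequence(paste0("bird_", i), c(list(c("Ld", "P")), extra))
  })
  build_database(seqs)
}

test_that("a universally shared motif is reported once, subpatterns suppressed", {
  db <- make_shared_motif_db()
  sw <- sweep_minsup(db, condition_id = "motif")
  top <- sw$levels[[1]]
  expect_equal(top$minsup, 1.0)
  expect_identical(top$reported$notation, "<{Ld,P}>")
  expect_false("<{Ld}>" %in% unlist(lapply(sw$levels, function(l) l$reported$notation)))
  # the deeper minority pattern surfaces once its level is reached
  deep <- unlist(lapply(sw$levels, function(l) l$reported$notation))
  expect_true(any(grepl("\\{E,W\\}", deep)))
})

test_that("levels with nothing frequent report an empty set", {
  db <- build_database(lapply(1:5, function(i) {
    broiler_sequence(paste0("b", i),
                     list(ethogram_codes()[i], ethogram_codes()[i + 5]))
  }))
  sw <- sweep_minsup(db, levels = c(1, 0.8, 0.6, 0.4, 0.2), condition_id = "x")
  for (lev in sw$levels) {
    if (lev$minsup > 0.2) expect_identical(nrow(lev$reported), 0L)
  }
  txt <- format_sweep_text(sw)
  expect_true(any(grepl("None", txt)))
})

test_that("a single-bird database reports its maximal pattern at every level once", {
  db <- build_database(list(broiler_sequence("solo", list(c("E", "W"), "D"))))
  sw <- sweep_minsup(db, levels = c(1, 0.9, 0.8), condition_id = "solo")
  expect_identical(sw$levels[[1]]$reported$notation, "<{E,W} {D}>")
  expect_identical(nrow(sw$levels[[2]]$reported), 0L)
  expect_identical(nrow(sw$levels[[3]]$reported), 0L)
  expect_identical(total_patterns(sw), 1L)
})

test_that("invalid level grids are rejected", {
  db <- example_database()
  expect_error(sweep_minsup(db, levels = c(0.5, 0.9)), "decreasing")
  expect_error(sweep_minsup(db, levels = c(1.2, 0.5)), "0, 1")
  expect_error(sweep_minsup(db, levels = numeric(0)), "0, 1")
})

test_that("no reported pattern is a subpattern of any same- or higher-level report", {
  for (seed in 61:66) {
    db <- random_db(seed, max_seqs = 8, max_windows = 5, max_alpha = 5,
                    max_len = 3)
    sw <- sweep_minsup(db, condition_id = "rand")
    seen <- list()
    redundant <- FALSE
    for (lev in sw$levels) {
      pats <- lev$reported$pattern
      for (i in seq_along(pats)) {
        for (q in seen) {
          if (pattern_subpattern(pats[[i]], q)) redundant <- TRUE
        }
        for (j in seq_along(pats)) {
          if (i != j && pattern_subpattern(pats[[i]], pats[[j]])) {
            redundant <- TRUE
          }
        }
      }
      seen <- c(seen, pats)
    }
    expect_false(redundant)
  }
})

test_that("sweep reports are complete: frequent patterns are reported or covered", {
  for (seed in 71:73) {
    db <- random_db(seed, max_seqs = 6, max_windows = 4, max_alpha = 4,
                    max_len = 3)
    lev <- 0.4
    sw <- sweep_minsup(db, levels = c(0.8, lev), condition_id = "c")
    m <- mine_gsp(db, lev)
    reported <- unlist(lapply(sw$levels, function(l) l$reported$pattern),
                       recursive = FALSE)
    covered <- vapply(seq_len(nrow(m)), function(i) {
      any(vapply(reported, function(q) {
        pattern_subpattern(m$pattern[[i]], q)
      }, TRUE))
    }, TRUE)
    expect_true(all(covered))
    # and every reported pattern at a level is frequent there
    for (l in sw$levels) {
      if (nrow(l$reported)) expect_true(all(l$reported$support >= l$minsup))
    }
  }
})

test_that("size tallies conserve the number of reported patterns", {
  for (cond in c("thermoneutral_plain", "heat_enriched")) {
    rep <- read_sweep_fixture(cond)
    tal <- tally_sizes(rep)
    per_level <- tapply(tal$count, tal$minsup, sum)
    for (lev in rep$levels) {
      if (nrow(lev$reported)) {
        expect_identical(unname(per_level[as.character(lev$minsup)]),
                         nrow(lev$reported))
      }
    }
    expect_identical(sum(tal$count), total_patterns(rep))
  }
})

test_that("packaged tables parse with verbatim labels and counts", {
  rep <- read_sweep_fixture("thermoneutral_plain")
  expect_identical(rep$condition_id, "thermoneutral_plain")
  expect_identical(rep$levels[[1]]$label, "1.0, 0.9 and 0.8")
  expect_equal(rep$levels[[1]]$levels, c(1.0, 0.9, 0.8))
  expect_identical(rep$levels[[1]]$reported$support_count, 10L)
  heat <- read_sweep_fixture("heat_plain")
  expect_identical(nrow(heat$levels[[1]]$reported), 0L)
  expect_equal(heat$levels[[1]]$levels, seq(1.0, 0.5, by = -0.1))
})

test_that("coverage and maximum size handle empty and full reports", {
  empty <- structure(list(condition_id = "none", levels = list()),
                     class = "sweep_report")
  cov <- behavior_coverage(empty)
  expect_length(cov$absent, 13L)
  expect_length(cov$used, 0L)
  expect_identical(max_reported_size(empty), 0L)
  rep <- read_sweep_fixture("thermoneutral_plain")
  expect_identical(max_reported_size(rep), 4L)
})

test_that("sweep reports export as JSON", {
  sw <- sweep_minsup(example_database(), levels = c(1, 0.5),
                     condition_id = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  write_sweep_json(sw, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(back$condition_id, "toy")
  expect_length(back$levels, 2L)
})
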