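test_that("element containment is an order-preserving subsequence with gaps", {
  expect_true(element_contained(c("Ld", "P"), c("Ld", "P", "F", "P")))
  expect_true(element_contained(c("P", "F", "P"), c("P", "F", "F", "P")))
  expect_false(element_contained(c("E", "W"), "E"))
  # multiplicity is respected
  expect_false(element_contained(c("P", "P"), c("P", "F")))
  expect_true(element_contained(c("P", "P"), c("P", "F", "P")))
})

test_that("sequence containment maps elements to strictly increasing windows", {
  db <- example_database()
  expect_true(sequence_contains(db[["broiler_1"]],
                                behavior_pattern(list("E", "D"))))
  # a single element requires co-occurrence in one window
  expect_false(sequence_contains(db[["broiler_2"]],
                                 behavior_pattern(list(c("Ld", "P")))))
  # any sequence contains the pattern made of its own elements
  expect_true(sequence_contains(db[["broiler_1"]],
                                behavior_pattern(db[["broiler_1"]]$elements)))
  # no window reuse: two elements cannot map to the same window
  one <- broiler_sequence("x", list(c("E", "W")))
  expect_false(sequence_contains(one, behavior_pattern(list("E", "W"))))
})

test_that("support counts each bird once and normalises by database size", {
  db <- example_database()
  s <- pattern_support(behavior_pattern(list("E", "D")), db)
  expect_identical(s$support_count, 1L)
  expect_equal(s$support, 0.5)
  expect_equal(pattern_support(behavior_pattern(list("Ld")), db)$support, 0.5)
  # a bird with many embeddings still counts once
  multi <- build_database(list(
    broiler_sequence("a", list(c("Ld", "P"), c("Ld", "P"), c("Ld", "P")))
  ))
  expect_identical(
    pattern_support(behavior_pattern(list(c("Ld", "P"))), multi)$support_count,
    1L)
  expect_equal(pattern_support(behavior_pattern(list("Ld")), multi)$support, 1)
})

test_that("the one-item join yields every ordered two-code arrangement except in-element repeats", {
  f1 <- list(behavior_pattern(list("Ld")), behavior_pattern(list("P")))
  cands <- generate_candidates(f1)
  expect_setequal(vapply(cands, format, ""),
                  c("<{Ld} {P}>", "<{P} {Ld}>", "<{Ld,P}>", "<{P,Ld}>",
                    "<{Ld} {Ld}>", "<{P} {P}>"))
  expect_length(generate_candidates(list()), 0L)
  expect_error(generate_candidates(list(
    behavior_pattern(list("Ld")),
    behavior_pattern(list(c("Ld", "P")))
  )), "identical item count")
})

test_that("the R and engine candidate generators agree on frequent sets", {
  # the exported R implementation and the C++ kernel used by mine_gsp must
  # produce the same candidate sets
  for (seed in 1:10) {
    db <- random_db(seed, max_seqs = 6, max_windows = 4, max_alpha = 5)
    mined <- mine_gsp(db, 0.4)
    for (k in unique(mined$item_count)) {
      sel <- mined$item_count == k
      encs <- attr(mined, "enc")[sel]
      r_cands <- broilerseq:::generate_candidates_enc(encs)
      c_cands <- broilerseq:::join_prune_cpp(encs)
      key <- function(l) sort(vapply(l, paste, "", collapse = ","))
      expect_identical(key(r_cands), key(c_cands))
    }
  }
})

test_that("worked-example mining matches the exhaustive oracle exactly", {
  db <- example_database()
  expect_identical(nrow(mine_gsp(db, 1.0)), 0L)
  m <- mine_gsp(db, 0.5)
  expect_identical(m$notation, worked_example_patterns_05)
  b <- brute_force_mine(db, 0.5, max_items = 3)
  expect_same_patterns(m, b)
})

test_that("threshold edge cases behave as a closed comparison", {
  db <- example_database()
  expect_error(mine_gsp(db, 0), "minsup")
  expect_error(mine_gsp(db, 1.2), "minsup")
  expect_error(brute_force_mine(db, -1), "minsup")
  # with n = 2, minsup 0.5 admits count 1 exactly
  expect_true(all(mine_gsp(db, 0.5)$support_count >= 1L))
  # every single occurring code is frequent at 1/n
  n <- db_size(db)
  m <- mine_gsp(db, 1 / n)
  singles <- m$notation[m$item_count == 1]
  expect_setequal(singles, c("<{Ld}>", "<{P}>", "<{W}>", "<{E}>", "<{D}>"))
})

test_that("the oracle enumerates everything at full support on identical sequences", {
  db <- build_database(list(
    broiler_sequence("a", list(c("E", "W"), "D")),
    broiler_sequence("b", list(c("E", "W"), "D"))
  ))
  b <- brute_force_mine(db, 1.0, max_items = 3)
  expect_true(all(b$support == 1))
  expect_true("<{E,W} {D}>" %in% b$notation)
  m <- mine_gsp(db, 1.0)
  expect_same_patterns(m, b)
})

test_that("the oracle refuses enumerations beyond its budget", {
  db <- build_database(list(broiler_sequence("a", as.list(ethogram_codes()))))
  expect_error(brute_force_mine(db, 0.5, max_items = 5), "budget")
})

test_that("mined patterns export as JSON lines", {
  m <- mine_gsp(example_database(), 0.5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_patterns_jsonl(m, path)
  lines <- readLines(path)
  expect_length(lines, nrow(m))
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$pattern, m$notation[1])
  expect_identical(rec$support_count, m$support_count[1])
})
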