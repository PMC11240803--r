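# Shared fixtures, built in code.

# A random small sequence database obeying the data invariants (window
# elements never contain adjacent duplicate codes). Sized for the brute-force
# oracle.
random_db <- function(seed, max_seqs = 10, max_windows = 6, max_alpha = 6,
                      max_len = 4) {
  set.seed(seed)
  alpha <- ethogram_codes()[seq_len(sample(3:max_alpha, 1))]
  n <- sample(3:max_seqs, 1)
  seqs <- lapply(seq_len(n), function(i) {
    nw <- sample(2:max_windows, 1)
    elements <- lapply(seq_len(nw), function(w) {
      len <- sample(0:max_len, 1)
      codes <- character(0)
      while (length(codes) < len) {
        cand <- sample(alpha, 1)
        if (!length(codes) || codes[length(codes)] != cand) {
          codes <- c(codes, cand)
        }
      }
      codes
    })
    broiler_sequence(paste0("bird_", i), elements)
  })
  build_database(seqs)
}

# Frozen expectation: complete frequent set of the two-bird worked example at
# minimum support 0.5, derived by exhaustive enumeration of all subpatterns
# of its two sequences.
worked_example_patterns_05 <- c(
  "<{Ld}>", "<{P}>", "<{W}>", "<{E}>", "<{D}>",
  "<{Ld} {P}>", "<{W} {D}>", "<{E} {W}>", "<{E} {D}>",
  "<{E} {W} {D}>"
)

expect_same_patterns <- function(a, b) {
  expect_identical(a$notation, b$notation)
  expect_identical(a$support_count, b$support_count)
  expect_equal(a$support, b$support)
  expect_identical(a$item_count, b$item_count)
  expect_identical(a$size, b$size)
}
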