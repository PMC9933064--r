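test_that("a short query is located exactly inside a longer reference", {
  a <- smith_waterman(c("the", "cat", "sat"),
                      c("a", "dog", "and", "the", "cat", "sat", "down"))
  expect_equal(a$ref_span, c(start = 4L, end = 7L))
  expect_equal(a$n_matches, 3L)
  expect_equal(a$similarity, 1.0)
  expect_identical(extract_correction(a, c("a", "dog", "and", "the", "cat",
                                           "sat", "down")),
                   c("the", "cat", "sat"))
})

test_that("empty query or reference yields the empty alignment", {
  for (a in list(smith_waterman(character(0), c("a", "b")),
                 smith_waterman(c("a", "b"), character(0)))) {
    expect_equal(a$score, 0)
    expect_equal(a$similarity, 0)
    expect_equal(unname(a$query_span[2] - a$query_span[1]), 0L)
    expect_identical(extract_correction(a, c("a", "b")), character(0))
  }
})

test_that("the transcript-excerpt pair scores 7 matches of 10 and fails the gate", {
  hyp <- normalize_text("fthe last question is there anything you want to tell")
  ref <- normalize_text(paste("en dan zei ze",
                              "the last—is there something you want to tell",
                              "en zo verder"))
  a <- smith_waterman(hyp, ref)
  expect_equal(a$n_matches, 7L)
  expect_equal(a$similarity, 0.70)
  expect_false(gate_alignment(a, 0.90))
  # the matched transcript slice is the correction despite the inserted word
  corr <- extract_correction(a, ref)
  expect_true(all(corr %in% ref))
  expect_true(all(c("something", "want", "tell") %in% corr))
})

test_that("gate accepts at the threshold boundary and rejects strictly below", {
  expect_true(gate_alignment(0.90, 0.90))
  expect_false(gate_alignment(0.0, 0.90))
  expect_true(gate_alignment(1.0, 0.90))
  expect_error(gate_alignment(0.5, 1.5))
})

test_that("raising the threshold never accepts more alignments", {
  set.seed(11)
  sims <- runif(50)
  thresholds <- seq(0, 1, by = 0.05)
  accepted <- vapply(thresholds,
                     function(t) sum(vapply(sims, gate_alignment, logical(1),
                                            threshold = t)),
                     numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("dynamic-programming score equals the exhaustive oracle", {
  set.seed(101)
  for (k in 1:60) {
    q <- random_tokens(sample(0:8, 1))
    r <- random_tokens(sample(0:8, 1))
    a <- smith_waterman(q, r)
    expect_equal(a$score, sw_oracle_score(q, r), label = paste(k))
    # the reported ops must reproduce the score and span lengths
    sc <- c(match = 2, mismatch = -1, gap_in_query = -1, gap_in_ref = -1)
    expect_equal(a$score, sum(sc[as.character(a$ops)]) + 0)
    expect_equal(sum(a$ops %in% c("match", "mismatch", "gap_in_query")),
                 unname(a$query_span["end"] - a$query_span["start"]))
    expect_equal(sum(a$ops %in% c("match", "mismatch", "gap_in_ref")),
                 unname(a$ref_span["end"] - a$ref_span["start"]))
  }
})

test_that("self-alignment is perfect and substrings are recovered exactly", {
  set.seed(13)
  vocab <- default_vocabulary()
  for (k in 1:25) {
    x <- sample(vocab, sample(1:12, 1))  # all-distinct tokens
    a <- smith_waterman(x, x)
    expect_equal(a$similarity, 1.0)
    expect_equal(a$ref_span, c(start = 1L, end = length(x) + 1L))

    ref <- sample(vocab, 40)
    len <- sample(1:8, 1)
    s <- sample(1:(40 - len + 1), 1)
    slice <- ref[s:(s + len - 1)]
    b <- smith_waterman(slice, ref)
    expect_equal(b$similarity, 1.0)
    expect_identical(extract_correction(b, ref), slice)
  }
})

test_that("tie-breaks make repeated and ambiguous alignments deterministic", {
  # query occurs twice in the reference: the earlier occurrence wins
  a <- smith_waterman(c("x", "y"), c("x", "y", "z", "x", "y"))
  expect_equal(a$ref_span, c(start = 1L, end = 3L))
  b <- smith_waterman(c("x", "y"), c("x", "y", "z", "x", "y"))
  expect_identical(glance(a), glance(b))
})

test_that("tidy() lays out one row per alignment operation", {
  a <- smith_waterman(c("the", "cat"), c("the", "dog", "cat"))
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(a$ops))
  expect_equal(sum(!is.na(td$query_index)),
               unname(a$query_span["end"] - a$query_span["start"]))
})

test_that("scoring schemes are validated", {
  expect_error(sw_scoring(match = 0), class = "curasr_bad_scoring")
  expect_error(sw_scoring(mismatch = 1), class = "curasr_bad_scoring")
  expect_error(sw_scoring(gap = 0.5), class = "curasr_bad_scoring")
})
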