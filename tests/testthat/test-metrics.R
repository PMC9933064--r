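test_that("edit counts on simple fixtures behave as expected", {
  x <- c("een", "twee", "drie", "vier", "vijf")
  e <- edit_ops(x, x)
  expect_equal(e$hits, 5)
  expect_equal(e$substitutions + e$insertions + e$deletions, 0)

  e2 <- edit_ops(c("a", "b", "c", "d"), character(0))
  expect_equal(e2$deletions, 4)
  expect_equal(wer(c("a", "b", "c", "d"), character(0)), 100)

  # the hit-preserving path wins ties: D + hit + I, not two substitutions
  e3 <- edit_ops(c("ab", "ba"), c("ba", "ab"))
  expect_equal(e3$hits, 1)
  expect_equal(e3$deletions, 1)
  expect_equal(e3$insertions, 1)
  expect_equal(e3$substitutions, 0)
  # a plain swap with no shared word is two substitutions
  e4 <- edit_ops(c("aa", "bb"), c("xx", "yy"))
  expect_equal(e4$substitutions, 2)
})

test_that("the transcript excerpt has one character insertion and 33.33% WER", {
  hyp <- normalize_text("fthe last question is there anything you want to tell")
  restored <- normalize_text("the last question is there anything you want to tell")
  e <- edit_ops(restored, hyp, level = "character")
  expect_equal(e$insertions, 1)
  expect_equal(e$substitutions, 0)
  expect_equal(e$deletions, 0)

  manual <- normalize_text("the last—is there something you want to tell")
  expect_equal(wer(manual, hyp), (2 + 1) / 9 * 100, tolerance = 1e-10)
})

test_that("wer handles single-insertion and empty-reference contracts", {
  ref <- strsplit("a b c d e f g h i j", " ")[[1]]
  expect_equal(wer(ref, c(ref, "extra")), 10)
  expect_error(wer(character(0), c("a")), class = "curasr_empty_ref")
  # insertions can push WER past 100%
  expect_gt(wer(c("a"), c("b", "c", "d")), 100)
})

test_that("decomposition identities hold on random pairs and WER=0 iff equal", {
  set.seed(202)
  for (k in 1:1000) {
    r <- random_tokens(sample(0:12, 1))
    h <- random_tokens(sample(0:12, 1))
    e <- edit_ops(r, h)
    expect_equal(e$hits + e$substitutions + e$deletions, length(r))
    expect_equal(e$hits + e$substitutions + e$insertions, length(h))
    if (length(r) > 0) {
      w <- wer(r, h)
      expect_equal(w == 0, identical(r, h))
    }
  }
})

test_that("edit counts attain the exhaustive minimal edit distance", {
  set.seed(303)
  for (k in 1:200) {
    r <- random_tokens(sample(0:6, 1), alphabet = c("aa", "bb", "cc"))
    h <- random_tokens(sample(0:6, 1), alphabet = c("aa", "bb", "cc"))
    e <- edit_ops(r, h)
    expect_equal(e$substitutions + e$insertions + e$deletions,
                 edit_distance_oracle(r, h), label = paste(k))
  }
})

test_that("edit distance agrees with utils::adist at character level", {
  set.seed(404)
  vocab <- default_vocabulary()
  for (k in 1:50) {
    r <- sample(vocab, sample(1:10, 1), replace = TRUE)
    h <- sample(vocab, sample(1:10, 1), replace = TRUE)
    e <- edit_ops(r, h, level = "character")
    expect_equal(e$substitutions + e$insertions + e$deletions,
                 as.integer(utils::adist(render_text(r), render_text(h))))
  }
})

test_that("error distributions pool counts per group and sum to 100", {
  # one pair with a single insertion
  d1 <- error_distribution(list(c("a", "b")), list(c("a", "b", "x")))
  expect_equal(d1$insertion_pct, 100)
  expect_equal(d1$substitution_pct + d1$deletion_pct, 0)

  # constructed pooled counts 7 insertions, 1 substitution, 2 deletions
  refs <- list(c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
               c("k", "l"))
  hyps <- list(c("a", "b", "c", "d", "e", "f", "g", "h", "Z", "j",
                 "p", "q", "r", "s", "t", "u", "v"),
               character(0))
  d2 <- error_distribution(refs, hyps, level = "word")
  expect_equal(d2$insertions, 7)
  expect_equal(d2$substitutions, 1)
  expect_equal(d2$deletions, 2)
  expect_equal(unlist(d2[, c("insertion_pct", "substitution_pct",
                             "deletion_pct")]),
               c(insertion_pct = 70, substitution_pct = 10,
                 deletion_pct = 20))
  expect_equal(d2$insertion_pct + d2$substitution_pct + d2$deletion_pct, 100,
               tolerance = 0.01)

  # error-free group is flagged, not divided by zero
  d3 <- error_distribution(list(c("a")), list(c("a")))
  expect_true(d3$zero_errors)
  expect_equal(d3$insertion_pct, 0)

  # per-group pooling keeps groups separate
  d4 <- error_distribution(c(refs, list(c("m"))), c(hyps, list(character(0))),
                           level = "word", groups = c("g1", "g1", "g2"))
  expect_equal(nrow(d4), 2)
  expect_equal(d4$deletion_pct[d4$group == "g2"], 100)
})

test_that("boxplot statistics use interpolated quartiles and 1.5 IQR whiskers", {
  s <- group_boxplot_stats(rep(25, 10))
  expect_equal(s$median, 25)
  expect_length(s$outliers[[1]], 0)

  v <- c(10, 20, 30, 40, 100)
  s2 <- group_boxplot_stats(v)
  expect_equal(s2$median, 30)
  expect_equal(s2$q1, unname(quantile(v, 0.25)))
  expect_equal(s2$q3, unname(quantile(v, 0.75)))
  # recomputed whisker rule decides the outlier status of 100
  out <- v[v < s2$q1 - 1.5 * s2$iqr | v > s2$q3 + 1.5 * s2$iqr]
  expect_identical(s2$outliers[[1]], out)
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)

  # element-wise larger group has the larger median
  s3 <- group_boxplot_stats(c(1, 2, 3, 11, 12, 13),
                            groups = rep(c("lo", "hi"), each = 3))
  expect_gte(s3$median[s3$group == "hi"], s3$median[s3$group == "lo"])
})
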