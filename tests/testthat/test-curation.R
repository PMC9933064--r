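make_world <- function(seed = 1, n_corpus = 2, n_utterances = 8,
                       n_val_utterances = 20, ...) {
  ivs <- lapply(seq_len(n_corpus), function(i) {
    quick_interview(seed * 100 + i, n_utterances = n_utterances, ...)
  })
  names(ivs) <- paste0("iv", seq_len(n_corpus))
  val_iv <- quick_interview(seed * 100 + 99, n_utterances = n_val_utterances,
                            words_per_utterance = c(15, 25), ...)
  ivs$validation <- val_iv
  list(interviews = ivs,
       corpus = ivs[seq_len(n_corpus)],
       validation = validation_from_interview(val_iv, "validation"))
}

test_that("a corrupting backend accepts some segments, all above the gate", {
  w <- make_world(seed = 3, n_corpus = 3)
  backend <- mock_backend(w$interviews, word_error_rate = 0.3, seed = 17)
  manifests <- lapply(names(w$corpus), function(id) {
    curate_pass(backend, w$corpus[[id]]$audio, w$corpus[[id]]$transcript,
                audio_id = id)
  })
  m <- do.call(rbind, manifests)
  frac <- mean(m$status == "accepted")
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  acc <- m[m$status == "accepted", ]
  expect_true(all(acc$similarity >= 0.90))
  # every correction is a contiguous slice of its interview's transcript
  for (k in seq_len(nrow(acc))) {
    tr <- render_text(w$interviews[[acc$audio_id[k]]]$transcript)
    expect_true(grepl(acc$correction_text[k], tr, fixed = TRUE))
  }
})

test_that("an empty transcript curates nothing, with a warning", {
  w <- make_world(seed = 4, n_corpus = 1, n_utterances = 2)
  backend <- perfect_backend(w$interviews)
  expect_warning(
    m <- curate_pass(backend, w$corpus$iv1$audio, character(0),
                     audio_id = "iv1"),
    class = "curasr_empty_transcript"
  )
  expect_equal(nrow(m), 0)
})

test_that("a backend failure marks the segment as error and continues", {
  w <- make_world(seed = 5, n_corpus = 1, n_utterances = 4)
  inner <- perfect_backend(w$interviews)
  calls <- new.env(); calls$n <- 0L
  flaky <- asr_backend(
    transcribe = function(audio, info) {
      calls$n <- calls$n + 1L
      if (calls$n == 2L) stop("backend glitch")
      inner$transcribe(audio, info)
    },
    finetune = function(pairs) invisible(NULL)
  )
  m <- curate_pass(flaky, w$corpus$iv1$audio, w$corpus$iv1$transcript,
                   audio_id = "iv1")
  expect_equal(sum(m$status == "error"), 1)
  expect_equal(sum(m$status == "accepted"), nrow(m) - 1)
})

test_that("a frozen backend plateaus immediately with two equal records", {
  w <- make_world(seed = 6)
  backend <- mock_backend(w$interviews, word_error_rate = 0.2,
                          improvement_factor = 1, seed = 2)
  run <- curate_iterate(backend, w$corpus, w$validation)
  expect_equal(run$records$iteration, c(0L, 1L))
  expect_equal(run$records$validation_wer_pct[1],
               run$records$validation_wer_pct[2])
  expect_equal(run$stop_reason, "plateau")
})

test_that("the improving backend drives WER down until it plateaus", {
  w <- make_world(seed = 7, n_corpus = 3)
  backend <- mock_backend(w$interviews, word_error_rate = 0.3,
                          improvement_factor = 0.5, seed = 11)
  run <- curate_iterate(backend, w$corpus, w$validation,
                        max_iterations = 10)
  r <- run$records
  expect_gte(nrow(r), 4)
  expect_true(all(diff(r$validation_wer_pct[1:4]) < 0))
  expect_true(all(diff(r$cumulative_accepted_samples) >= 0))
  expect_true(run$stop_reason %in%
                c("plateau", "wer_increased", "max_iterations"))
})

test_that("max_iterations caps a still-improving run", {
  w <- make_world(seed = 8)
  backend <- mock_backend(w$interviews, word_error_rate = 0.3,
                          improvement_factor = 0.5, seed = 3)
  run <- curate_iterate(backend, w$corpus, w$validation, max_iterations = 2)
  expect_equal(run$records$iteration, c(0L, 1L, 2L))
  expect_equal(run$stop_reason, "max_iterations")
})

test_that("a hopeless backend accepts nothing and the loop stops", {
  w <- make_world(seed = 9, n_corpus = 1)
  backend <- mock_backend(w$interviews, word_error_rate = 1,
                          improvement_factor = 1, seed = 4)
  run <- curate_iterate(backend, w$corpus, w$validation)
  expect_equal(run$stop_reason, "no_accepted_samples")
  expect_equal(nrow(run$records), 1)
  expect_error(curate_iterate(backend, w$corpus, list()),
               class = "curasr_config_error")
})

test_that("identical seeds and config reproduce identical runs", {
  run_once <- function() {
    w <- make_world(seed = 10)
    backend <- mock_backend(w$interviews, word_error_rate = 0.3,
                            improvement_factor = 0.5, seed = 12)
    curate_iterate(backend, w$corpus, w$validation, max_iterations = 4)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$records, b$records)
  expect_identical(a$manifest, b$manifest)
})

test_that("mock backend error rates are recovered before and after finetune", {
  # large word count, cheap audio: the backend never reads the waveform
  ivs <- lapply(1:6, function(i) {
    generate_interview(synth_spec(n_utterances = 24, sample_rate = 500,
                                  words_per_utterance = c(60, 80),
                                  seed = 400 + i))
  })
  names(ivs) <- paste0("big", 1:6)
  backend <- mock_backend(ivs, word_error_rate = 0.3,
                          improvement_factor = 0.5, seed = 21)
  measure <- function() {
    refs <- list(); hyps <- list()
    for (id in names(ivs)) {
      u <- ivs[[id]]$utterances
      for (k in seq_len(nrow(u))) {
        info <- list(audio_id = id, start_s = u$start_s[k], end_s = u$end_s[k])
        refs[[length(refs) + 1]] <- u$tokens[[k]]
        hyps[[length(hyps) + 1]] <- normalize_text(
          backend$transcribe(NULL, info))
      }
    }
    expect_gte(sum(lengths(refs)), 10000)
    corpus_wer(refs, hyps)
  }
  before <- measure()
  backend$finetune(list())
  after <- measure()
  # expected measured WER: total rate minus the deletion x insertion
  # composition term (a deletion with an insertion at or just before it is
  # one substitution under minimal edits, not two errors)
  expected <- function(rate) {
    p <- rate / 3
    100 * (3 * p - p * (1 - (1 - p)^2))
  }
  expect_lt(abs(before - expected(0.3)), 2)
  expect_lt(abs(after - expected(0.15)), 2)
})

test_that("run summaries and plots expose the iteration history", {
  w <- make_world(seed = 12, n_corpus = 1, n_utterances = 6)
  backend <- mock_backend(w$interviews, word_error_rate = 0.2,
                          improvement_factor = 0.5, seed = 5)
  run <- curate_iterate(backend, w$corpus, w$validation, max_iterations = 3)
  td <- tidy(run)
  expect_identical(td, run$records)
  g <- glance(run)
  expect_equal(g$initial_wer_pct, td$validation_wer_pct[1])
  expect_s3_class(autoplot(run), "ggplot")
})
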