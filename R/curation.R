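#' ASR backend contract
#'
#' A backend is any object of class `"asr_backend"`: a list with
#' `transcribe(audio, info)` returning raw text for an audio segment,
#' `finetune(pairs)` updating the backend state from accepted
#' (segment, correction) pairs, a `descriptor` string identifying
#' model/version, and optional `snapshot()` / `restore(state)` functions so
#' the iteration loop can keep the best model when the validation WER turns
#' up. `transcribe` must be deterministic for fixed backend state and input.
#' Real neural backends plug in through this same surface; the package ships
#' mock backends whose truth oracle is the synthetic-interview ground truth.
#'
#' @param transcribe,finetune,descriptor,snapshot,restore Contract members.
#' @return An object of class `"asr_backend"`.
#' @export
asr_backend <- function(transcribe, finetune, descriptor = "backend",
                        snapshot = NULL, restore = NULL) {
  stopifnot(is.function(transcribe), is.function(finetune))
  structure(
    list(transcribe = transcribe, finetune = finetune,
         descriptor = descriptor, snapshot = snapshot, restore = restore),
    class = "asr_backend"
  )
}

#' @export
print.asr_backend <- function(x, ...) {
  cat("<asr_backend>", x$descriptor, "\n")
  invisible(x)
}

# deterministic per-call seed from backend seed, state version and segment id
.segment_seed <- function(seed, version, audio_id, start_s) {
  key <- (as.numeric(seed) * 1000003 + as.numeric(version) * 10007 +
            sum(utf8ToInt(audio_id)) * 97 + round(start_s * 1000))
  as.integer(key %% 2147483629)
}

.lookup_truth <- function(interviews, info) {
  iv <- interviews[[info$audio_id]]
  if (is.null(iv)) {
    abort(paste0("mock backend has no ground truth for '", info$audio_id, "'"),
          class = "curasr_unknown_audio")
  }
  mid <- (iv$utterances$start_s + iv$utterances$end_s) / 2
  hit <- mid >= info$start_s & mid < info$end_s
  unlist(iv$utterances$tokens[hit]) %||% character(0)
}

#' Mock ASR backend with a controllable, improvable error rate
#'
#' A test double for a finetunable acoustic model. `transcribe` returns the
#' segment's true text (looked up in the synthetic interviews' ground truth
#' by audio id and time span) with words independently corrupted at the
#' current total word error rate, split across insertion/deletion/
#' substitution by `error_split`. `finetune` multiplies the internal error
#' rate by `improvement_factor`, emulating a model that improves when given
#' more curated data. Corruption is seeded by (backend seed, state version,
#' segment identity), so runs are reproducible.
#'
#' @param interviews Named list of [generate_interview()] results; the names
#'   are the audio ids the backend recognises.
#' @param word_error_rate Initial total corruption rate in `[0, 1]`.
#' @param improvement_factor Multiplier applied to the rate at each
#'   finetune, in `(0, 1]` (1 = frozen backend).
#' @param seed Integer seed for the corruption stream.
#' @param error_split Proportions of the total rate assigned to insertion,
#'   deletion and substitution (normalised to sum to 1). Default equal
#'   thirds.
#' @return An [asr_backend()].
#' @export
mock_backend <- function(interviews, word_error_rate = 0.3,
                         improvement_factor = 0.5, seed = 1L,
                         error_split = c(insertion = 1, deletion = 1,
                                         substitution = 1) / 3) {
  if (!(is.numeric(word_error_rate) && word_error_rate >= 0 &&
        word_error_rate <= 1)) {
    abort("`word_error_rate` must be in [0, 1]", class = "curasr_bad_rate")
  }
  if (!(is.numeric(improvement_factor) && improvement_factor > 0 &&
        improvement_factor <= 1)) {
    abort("`improvement_factor` must be in (0, 1]", class = "curasr_bad_rate")
  }
  stopifnot(is.list(interviews), !is.null(names(interviews)),
            all(names(interviews) != ""))
  split <- error_split / sum(error_split)
  state <- new.env(parent = emptyenv())
  state$rate <- word_error_rate
  state$version <- 0L
  vocab <- interviews[[1]]$spec$vocabulary

  transcribe <- function(audio, info) {
    truth <- .lookup_truth(interviews, info)
    rates <- c(insertion = state$rate * split[["insertion"]],
               deletion = state$rate * split[["deletion"]],
               substitution = state$rate * split[["substitution"]])
    out <- corrupt_text(truth, rates, vocabulary = vocab,
                        seed = .segment_seed(seed, state$version,
                                             info$audio_id, info$start_s))
    render_text(out)
  }
  finetune <- function(pairs) {
    if (improvement_factor < 1) {  # factor 1 = frozen backend, a true no-op
      state$rate <- state$rate * improvement_factor
      state$version <- state$version + 1L
    }
    invisible(state$rate)
  }
  asr_backend(
    transcribe, finetune,
    descriptor = sprintf("mock(rate=%g, factor=%g, seed=%d)",
                         word_error_rate, improvement_factor,
                         as.integer(seed)),
    snapshot = function() as.list(state),
    restore = function(s) {
      state$rate <- s$rate
      state$version <- s$version
      invisible(NULL)
    }
  )
}

#' @describeIn mock_backend A backend that always returns the true text.
#' @export
perfect_backend <- function(interviews) {
  b <- mock_backend(interviews, word_error_rate = 0, improvement_factor = 1)
  b$descriptor <- "perfect(oracle)"
  b
}

.empty_manifest <- function() {
  tibble(audio_id = character(0), start_s = numeric(0), end_s = numeric(0),
         hypothesis_text = character(0), correction_text = character(0),
         similarity = numeric(0), status = character(0))
}

#' One curation pass over a recording
#'
#' Splits the recording at silences, transcribes each segment with the
#' backend, locally aligns the normalized hypothesis against the full manual
#' transcript, and applies the similarity gate: segments at or above the
#' threshold are accepted and carry the matched transcript slice as their
#' correction; segments below it are discarded. A backend failure on a
#' segment marks that segment `"error"` and the pass continues.
#'
#' @param backend An [asr_backend()].
#' @param audio The full recording, an [audio_signal()].
#' @param transcript The full manual transcript as normalized tokens.
#' @param seg_config A [segmenter_config()].
#' @param threshold Similarity gate in `[0, 1]`. Default 0.90.
#' @param scoring A [sw_scoring()].
#' @param audio_id Identifier recorded in the manifest.
#' @return A manifest tibble: `audio_id`, `start_s`, `end_s`,
#'   `hypothesis_text`, `correction_text` (NA when discarded), `similarity`,
#'   `status` (`accepted` / `discarded` / `error`).
#' @export
curate_pass <- function(backend, audio, transcript,
                        seg_config = segmenter_config(), threshold = 0.9,
                        scoring = sw_scoring(), audio_id = "audio") {
  stopifnot(inherits(backend, "asr_backend"), threshold >= 0, threshold <= 1)
  transcript <- as.character(transcript)
  if (length(transcript) == 0) {
    warn("empty transcript: no segments curated",
         class = "curasr_empty_transcript")
    return(.empty_manifest())
  }
  spans <- split_recursive(audio, seg_config)
  if (nrow(spans) == 0) return(.empty_manifest())

  rows <- purrr::pmap(spans, function(start_s, end_s, duration_s) {
    info <- list(audio_id = audio_id, start_s = start_s, end_s = end_s)
    raw <- tryCatch(
      backend$transcribe(slice_audio(audio, start_s, end_s), info),
      error = function(e) e
    )
    if (inherits(raw, "error")) {
      return(tibble(audio_id = audio_id, start_s = start_s, end_s = end_s,
                    hypothesis_text = NA_character_,
                    correction_text = NA_character_,
                    similarity = NA_real_, status = "error"))
    }
    hyp <- normalize_text(raw)
    aln <- smith_waterman(hyp, transcript, scoring)
    accepted <- gate_alignment(aln, threshold)
    correction <- if (accepted) extract_correction(aln, transcript) else NULL
    accepted <- accepted && length(correction) > 0
    tibble(
      audio_id = audio_id, start_s = start_s, end_s = end_s,
      hypothesis_text = render_text(hyp),
      correction_text = if (accepted) render_text(correction) else
        NA_character_,
      similarity = aln$similarity,
      status = if (accepted) "accepted" else "discarded"
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a validation set from a synthetic interview
#'
#' One validation item per planted utterance: the utterance's audio span and
#' its true text as the reference. Keep validation interviews disjoint from
#' the curation corpus.
#'
#' @param interview A [generate_interview()] result.
#' @param audio_id The id under which the backend knows this interview.
#' @return A list of items with fields `audio`, `info`, `reference`.
#' @export
validation_from_interview <- function(interview, audio_id) {
  stopifnot(inherits(interview, "synth_interview"))
  purrr::pmap(interview$utterances, function(start_s, end_s, text, tokens) {
    list(
      audio = slice_audio(interview$audio, start_s, end_s),
      info = list(audio_id = audio_id, start_s = start_s, end_s = end_s),
      reference = tokens
    )
  })
}

.validation_wer <- function(backend, validation) {
  hyps <- purrr::map(validation, function(v) {
    normalize_text(backend$transcribe(v$audio, v$info))
  })
  refs <- purrr::map(validation, "reference")
  corpus_wer(refs, hyps)
}

#' Iterative corpus curation with backend finetuning
#'
#' The full curation loop: measure the initial backend's validation WER
#' (iteration 0, zero accepted samples), then repeatedly curate the whole
#' corpus with the newest backend, finetune on all accepted pairs
#' accumulated so far, and re-measure WER on the fixed validation set. The
#' loop stops when the WER has not decreased by more than `epsilon`
#' percentage points (on an increase the previous backend state is restored
#' when the backend supports snapshots), when a pass accepts nothing, or at
#' `max_iterations`.
#'
#' @param backend The initial [asr_backend()].
#' @param corpus List of recordings to curate: each element a list with
#'   `audio` ([audio_signal()]), `transcript` (token vector) and `audio_id`,
#'   or a `synth_interview` (ids are then taken from the list's names).
#' @param validation Non-empty list of validation items (see
#'   [validation_from_interview()]); must be disjoint from the corpus.
#' @param seg_config,threshold,scoring Passed to [curate_pass()].
#' @param epsilon Minimum WER decrease (percentage points) counted as
#'   improvement. Default 0.
#' @param max_iterations Safety cap on finetune iterations. Default 10.
#' @return An object of class `"curation_run"`: `records` (tibble with
#'   `iteration`, `cumulative_accepted_samples`, `validation_wer_pct`),
#'   `stop_reason`, `manifest` (all passes' manifests with an
#'   `iteration_index` column), and the final `backend`.
#' @export
curate_iterate <- function(backend, corpus, validation,
                           seg_config = segmenter_config(), threshold = 0.9,
                           scoring = sw_scoring(), epsilon = 0,
                           max_iterations = 10) {
  stopifnot(inherits(backend, "asr_backend"), max_iterations >= 1)
  if (length(validation) == 0) {
    abort("validation set must be non-empty", class = "curasr_config_error")
  }
  corpus <- purrr::imap(corpus, function(item, nm) {
    if (inherits(item, "synth_interview")) {
      item <- list(audio = item$audio, transcript = item$transcript,
                   audio_id = if (is.character(nm) && nzchar(nm)) nm else
                     paste0("interview_", nm))
    }
    stopifnot(inherits(item$audio, "audio_signal"),
              is.character(item$audio_id))
    item
  })

  records <- tibble(iteration = 0L, cumulative_accepted_samples = 0L,
                    validation_wer_pct = .validation_wer(backend, validation))
  pool <- new.env(parent = emptyenv())
  manifests <- list()
  stop_reason <- "max_iterations"
  prev_wer <- records$validation_wer_pct[1]

  for (it in seq_len(max_iterations)) {
    manifest <- purrr::map(corpus, function(item) {
      curate_pass(backend, item$audio, item$transcript,
                  seg_config = seg_config, threshold = threshold,
                  scoring = scoring, audio_id = item$audio_id)
    }) |> dplyr::bind_rows()
    manifest$iteration_index <- it
    manifests[[it]] <- manifest

    acc <- manifest[manifest$status == "accepted", , drop = FALSE]
    for (k in seq_len(nrow(acc))) {
      key <- sprintf("%s@%.4f-%.4f", acc$audio_id[k], acc$start_s[k],
                     acc$end_s[k])
      pool[[key]] <- list(
        info = list(audio_id = acc$audio_id[k], start_s = acc$start_s[k],
                    end_s = acc$end_s[k]),
        correction = normalize_text(acc$correction_text[k])
      )
    }
    cumulative <- length(ls(pool))
    if (cumulative == 0) {
      stop_reason <- "no_accepted_samples"
      break
    }

    snap <- if (is.function(backend$snapshot)) backend$snapshot() else NULL
    backend$finetune(mget(ls(pool), envir = pool))
    new_wer <- .validation_wer(backend, validation)
    records <- dplyr::bind_rows(records, tibble(
      iteration = it, cumulative_accepted_samples = cumulative,
      validation_wer_pct = new_wer
    ))
    if (prev_wer - new_wer <= epsilon) {
      if (new_wer > prev_wer && !is.null(snap) &&
          is.function(backend$restore)) {
        backend$restore(snap)
        stop_reason <- "wer_increased"
      } else {
        stop_reason <- "plateau"
      }
      break
    }
    prev_wer <- new_wer
  }

  structure(
    list(records = records, stop_reason = stop_reason,
         manifest = dplyr::bind_rows(manifests), backend = backend),
    class = "curation_run"
  )
}

#' @export
print.curation_run <- function(x, ...) {
  cat("<curation_run>", nrow(x$records), "recorded iterations; stop:",
      x$stop_reason, "\n")
  print(x$records)
  invisible(x)
}

#' @describeIn curate_iterate Per-iteration records as a tibble.
#' @param x A `curation_run`.
#' @param ... Unused.
#' @export
tidy.curation_run <- function(x, ...) x$records

#' @describeIn curate_iterate One-row run summary.
#' @export
glance.curation_run <- function(x, ...) {
  r <- x$records
  tibble(
    n_iterations = max(r$iteration),
    initial_wer_pct = r$validation_wer_pct[1],
    final_wer_pct = r$validation_wer_pct[nrow(r)],
    best_wer_pct = min(r$validation_wer_pct),
    total_accepted_samples = max(r$cumulative_accepted_samples),
    stop_reason = x$stop_reason
  )
}

#' @describeIn curate_iterate Validation WER (and cumulative accepted
#'   samples, as point size) across iterations.
#' @param object A `curation_run`.
#' @export
autoplot.curation_run <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$validation_wer_pct)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$cumulative_accepted_samples)) +
    ggplot2::scale_size_continuous(name = "accepted samples") +
    ggplot2::labs(x = "iteration", y = "validation WER (%)") +
    ggplot2::theme_minimal()
}
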