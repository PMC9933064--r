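#' Default synthetic vocabulary
#'
#' Two hundred common Dutch words over the restricted alphabet; stable under
#' normalization, so synthetic transcripts round-trip exactly.
#'
#' @return A character vector of 200 words.
#' @export
default_vocabulary <- function() {
  path <- system.file("extdata", "vocab_nl.txt", package = "curasr",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Specification for a synthetic interview fixture
#'
#' Describes a synthetic long-form "interview": a sequence of utterances
#' (energy bursts carrying known word sequences) separated by silences of
#' controllable duration, over a low noise floor. The generated signal is
#' not speech — the segmentation pipeline only ever inspects frame energy —
#' but boundaries and per-utterance texts are known exactly, so every
#' pipeline stage can be tested against planted ground truth.
#'
#' @param n_utterances Number of utterances. Default 12.
#' @param utterance_duration_s Length-2 range of utterance durations (s).
#'   Default `c(2, 6)`.
#' @param silence_duration_ms Length-2 range of inter-utterance silence
#'   durations (ms). Default `c(300, 800)`, comfortably above the default
#'   250 ms first-pass minimum silence.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param speech_model `"band_noise"` (Gaussian noise bursts) or
#'   `"tone_burst"` (per-utterance sine). Default `"band_noise"`.
#' @param speech_level_dbfs RMS level of utterance audio (dBFS). Default -20.
#' @param noise_floor_dbfs RMS level of the background floor (dBFS).
#'   Default -60, well below the default -40 dBFS silence threshold.
#' @param vocabulary Words utterance texts are drawn from.
#' @param words_per_utterance Length-2 integer range. Default `c(5, 15)`.
#' @param error_rates Named numeric `c(insertion=, deletion=, substitution=)`
#'   word-level corruption rates used when deriving noisy hypotheses.
#'   Default `c(0.05, 0.10, 0.08)`.
#' @param group_label Optional speaker-group label attached to the interview.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_utterances = 12,
                       utterance_duration_s = c(2, 6),
                       silence_duration_ms = c(300, 800),
                       sample_rate = 16000,
                       speech_model = c("band_noise", "tone_burst"),
                       speech_level_dbfs = -20,
                       noise_floor_dbfs = -60,
                       vocabulary = default_vocabulary(),
                       words_per_utterance = c(5, 15),
                       error_rates = c(insertion = 0.05, deletion = 0.10,
                                       substitution = 0.08),
                       group_label = NULL,
                       seed = 1L) {
  speech_model <- match.arg(speech_model)
  stopifnot(n_utterances >= 0, length(utterance_duration_s) == 2,
            length(silence_duration_ms) == 2, sample_rate > 0,
            speech_level_dbfs > noise_floor_dbfs,
            length(words_per_utterance) == 2,
            all(error_rates >= 0), all(error_rates <= 1),
            length(vocabulary) >= 2)
  structure(
    list(n_utterances = as.integer(n_utterances),
         utterance_duration_s = utterance_duration_s,
         silence_duration_ms = silence_duration_ms,
         sample_rate = as.integer(sample_rate),
         speech_model = speech_model,
         speech_level_dbfs = speech_level_dbfs,
         noise_floor_dbfs = noise_floor_dbfs,
         vocabulary = vocabulary,
         words_per_utterance = as.integer(words_per_utterance),
         error_rates = error_rates,
         group_label = group_label,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

.dbfs_to_rms <- function(dbfs) 10^(dbfs / 20)

#' Generate a synthetic interview
#'
#' Produces audio with planted utterances and silences, the full transcript
#' (the concatenation of per-utterance texts, mimicking an untimed manual
#' transcript), and exact ground-truth boundaries. Deterministic given the
#' spec's seed. A degenerate spec with zero utterances yields one second of
#' noise floor and an empty transcript.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `"synth_interview"`: `audio` ([audio_signal()]),
#'   `transcript` (token vector), `utterances` (tibble with `start_s`,
#'   `end_s`, `text`, and list-column `tokens`), `group_label`, `spec`.
#' @export
generate_interview <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sr <- spec$sample_rate
  withr::with_seed(spec$seed, {
    floor_rms <- .dbfs_to_rms(spec$noise_floor_dbfs)
    speech_rms <- .dbfs_to_rms(spec$speech_level_dbfs)
    if (spec$n_utterances == 0) {
      audio <- audio_signal(stats::rnorm(sr) * floor_rms, sr)
      return(structure(
        list(audio = audio, transcript = character(0),
             utterances = tibble(start_s = numeric(0), end_s = numeric(0),
                                 text = character(0), tokens = list()),
             group_label = spec$group_label, spec = spec),
        class = "synth_interview"
      ))
    }
    n <- spec$n_utterances
    utt_dur <- runif(n, spec$utterance_duration_s[1],
                     spec$utterance_duration_s[2])
    sil_dur <- runif(n + 1, spec$silence_duration_ms[1],
                     spec$silence_duration_ms[2]) / 1000
    n_words <- sample(spec$words_per_utterance[1]:spec$words_per_utterance[2],
                      n, replace = TRUE)
    tokens <- lapply(n_words, function(k) {
      sample(spec$vocabulary, k, replace = TRUE)
    })
    freqs <- runif(n, 150, 1000)  # tone_burst frequencies

    # snap every boundary to whole samples so recorded times are exact
    starts <- numeric(n); ends <- numeric(n)
    cursor <- round(sil_dur[1] * sr)
    pieces <- list(stats::rnorm(cursor))
    for (i in seq_len(n)) {
      len <- round(utt_dur[i] * sr)
      starts[i] <- cursor / sr
      burst <- switch(spec$speech_model,
        band_noise = stats::rnorm(len) * speech_rms,
        tone_burst = sin(2 * pi * freqs[i] * seq_len(len) / sr) *
          speech_rms * sqrt(2)
      )
      pieces[[length(pieces) + 1L]] <- burst / floor_rms  # rescaled below
      cursor <- cursor + len
      ends[i] <- cursor / sr
      gap <- round(sil_dur[i + 1] * sr)
      pieces[[length(pieces) + 1L]] <- stats::rnorm(gap)
      cursor <- cursor + gap
    }
    # assemble: floor noise everywhere, bursts added on top
    samples <- numeric(cursor)
    pos <- 0L
    for (p in pieces) {
      samples[pos + seq_along(p)] <- p
      pos <- pos + length(p)
    }
    # pieces stored in floor-noise units for silences and burst/floor_rms
    # for speech; scale once so silences sit at the floor level
    samples <- samples * floor_rms
    samples <- samples + stats::rnorm(length(samples)) * floor_rms * 0.5
    samples <- pmax(pmin(samples, 1), -1)

    structure(
      list(
        audio = audio_signal(samples, sr),
        transcript = unlist(tokens) %||% character(0),
        utterances = tibble(
          start_s = starts, end_s = ends,
          text = vapply(tokens, render_text, character(1)),
          tokens = tokens
        ),
        group_label = spec$group_label,
        spec = spec
      ),
      class = "synth_interview"
    )
  })
}

#' @export
print.synth_interview <- function(x, ...) {
  cat(sprintf("<synth_interview> %d utterances, %.1f s audio, %d words\n",
              nrow(x$utterances), x$audio$duration_s, length(x$transcript)))
  invisible(x)
}

#' Corrupt a token sequence at known word-level error rates
#'
#' The noise model behind the mock ASR backend: independently per word, a
#' single draw decides deletion (with the given probability), substitution
#' by a different vocabulary word, or keep; independently, after each word a
#' vocabulary word is inserted with the insertion probability. Deterministic
#' given the seed.
#'
#' @param truth Character vector of true tokens.
#' @param rates Named numeric `c(insertion=, deletion=, substitution=)`,
#'   each in `[0, 1]` with `deletion + substitution <= 1`.
#' @param vocabulary Words to draw substitutions/insertions from.
#' @param seed Integer seed.
#' @return The corrupted token vector.
#' @export
corrupt_text <- function(truth, rates, vocabulary = default_vocabulary(),
                         seed = 1L) {
  stopifnot(all(c("insertion", "deletion", "substitution") %in% names(rates)),
            all(rates >= 0), all(rates <= 1),
            rates[["deletion"]] + rates[["substitution"]] <= 1)
  truth <- as.character(truth)
  if (length(truth) == 0) return(character(0))
  withr::with_seed(as.integer(seed), {
    u <- runif(length(truth))
    ins <- runif(length(truth)) < rates[["insertion"]]
    out <- vector("list", length(truth))
    for (i in seq_along(truth)) {
      w <- truth[i]
      kept <- if (u[i] < rates[["deletion"]]) {
        character(0)
      } else if (u[i] < rates[["deletion"]] + rates[["substitution"]]) {
        sub <- sample(setdiff(vocabulary, w), 1)
        sub
      } else {
        w
      }
      if (ins[i]) kept <- c(kept, sample(vocabulary, 1))
      out[[i]] <- kept
    }
    unlist(out) %||% character(0)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
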