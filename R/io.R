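#' Read a WAV file as a mono audio signal
#'
#' Parses RIFF/WAVE containers with PCM 8/16/24/32-bit or IEEE float 32/64
#' sample formats, 1 or 2 channels. Stereo is downmixed by averaging the
#' channels; samples are scaled to `[-1, 1]`; when `target_rate` differs
#' from the file's rate the signal is resampled (polyphase, via the signal
#' package).
#'
#' @param path Path to a `.wav` file.
#' @param target_rate Internal sampling rate in Hz, or `NULL` to keep the
#'   file's rate. Default 16000.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, target_rate = 16000) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    abort(paste0("not a RIFF/WAVE file: ", path), class = "curasr_io_error")
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(paste0("not a RIFF/WAVE file: ", path), class = "curasr_io_error")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(paste0("missing fmt/data chunk in WAV file: ", path),
          class = "curasr_io_error")
  }
  if (!fmt$n_channels %in% c(1L, 2L)) {
    abort(paste0("unsupported channel count in ", path), class = "curasr_io_error")
  }

  x <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      switch(as.character(fmt$bits),
        "8" = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                                  signed = FALSE)) - 128) / 128,
        "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                       signed = TRUE, endian = "little") / 32768,
        "24" = {
          n <- length(data_raw) %/% 3
          b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
          v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
          v <- ifelse(v >= 8388608, v - 16777216, v)
          v / 8388608
        },
        "32" = readBin(data_raw, "integer", length(data_raw) / 4, 4,
                       signed = TRUE, endian = "little") / 2147483648,
        abort(paste0("unsupported PCM bit depth in ", path),
              class = "curasr_io_error")
      )
    },
    "3" = {  # IEEE float
      readBin(data_raw, "double", length(data_raw) %/% (fmt$bits / 8),
              fmt$bits / 8, endian = "little")
    },
    abort(paste0("unsupported WAV sample format in ", path),
          class = "curasr_io_error")
  )

  if (fmt$n_channels == 2L) {
    n <- (length(x) %/% 2) * 2
    x <- (x[seq(1, n, by = 2)] + x[seq(2, n, by = 2)]) / 2
  }
  audio <- audio_signal(x, fmt$sample_rate)
  if (!is.null(target_rate) && target_rate != fmt$sample_rate) {
    audio <- resample_audio(audio, target_rate)
  }
  audio
}

#' Write an audio signal as 16-bit PCM mono WAV
#'
#' @param path Output path.
#' @param audio An [audio_signal()].
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, audio) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- pmax(pmin(audio$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(audio$sample_rate, con, size = 4, endian = "little")
  writeBin(audio$sample_rate * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample an audio signal
#'
#' Rational-factor polyphase resampling via [signal::resample()].
#'
#' @param audio An [audio_signal()].
#' @param rate Target rate in Hz.
#' @return An [audio_signal()] at `rate`.
#' @export
resample_audio <- function(audio, rate) {
  stopifnot(inherits(audio, "audio_signal"), rate > 0)
  if (rate == audio$sample_rate) return(audio)
  g <- .gcd(as.integer(rate), audio$sample_rate)
  y <- signal::resample(audio$samples, rate / g, audio$sample_rate / g)
  audio_signal(y, rate)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Read and write segment manifests (JSONL)
#'
#' One JSON object per line describing a curated segment: `audio_id`,
#' `start_s`, `end_s`, `hypothesis_text`, `correction_text`, `similarity`,
#' `status`, plus any extra fields (e.g. `speaker_group`,
#' `iteration_index`), which round-trip unchanged. On read, gate soundness
#' is re-checked: a record whose similarity reaches `threshold` but is
#' marked `discarded` — or an `accepted` record without a correction — is a
#' validation error.
#'
#' @param path File path.
#' @param threshold Similarity gate the manifest was produced with (used for
#'   consistency checking on read). Default 0.90.
#' @return `read_manifest()` returns a tibble (zero rows for an empty
#'   file); `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path, threshold = 0.9) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(.empty_manifest())
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) e)
    if (inherits(rec, "error")) {
      abort(sprintf("malformed manifest line %d in %s", i, path),
            class = "curasr_io_error")
    }
    rec[vapply(rec, is.null, logical(1))] <- NA
    as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  if (!all(c("start_s", "end_s", "status") %in% names(out))) {
    abort(paste0("manifest missing required fields: ", path),
          class = "curasr_io_error")
  }
  if (any(out$start_s >= out$end_s)) {
    abort("manifest has start_s >= end_s", class = "curasr_manifest_invalid")
  }
  if (!all(out$status %in% c("accepted", "discarded", "error"))) {
    abort("manifest has unknown status values",
          class = "curasr_manifest_invalid")
  }
  ok_sim <- !is.na(out$similarity)
  if (any(out$status == "discarded" & ok_sim & out$similarity >= threshold)) {
    abort("manifest record marked discarded despite similarity >= threshold",
          class = "curasr_manifest_invalid")
  }
  if (any(out$status == "accepted" &
          (is.na(out$correction_text) | !nzchar(out$correction_text)))) {
    abort("accepted manifest record lacks a correction",
          class = "curasr_manifest_invalid")
  }
  out
}

#' @rdname read_manifest
#' @param records A manifest tibble (as produced by [curate_pass()]).
#' @export
write_manifest <- function(path, records) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write the per-iteration log of a curation run as CSV
#'
#' Columns: `iteration`, `cumulative_accepted_samples`,
#' `validation_wer_pct`.
#'
#' @param run A `curation_run` (or its records tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iteration_log <- function(run, path) {
  records <- if (inherits(run, "curation_run")) run$records else run
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-group evaluation report as CSV
#'
#' Joins boxplot statistics of per-pair WERs with the pooled error-type
#' distribution, one row per speaker group.
#'
#' @param references,hypotheses Parallel lists of token vectors.
#' @param groups Group label per pair (or `NULL` for one pooled group).
#' @param path Output CSV path.
#' @param level Level for the error-type distribution. Default
#'   `"character"`.
#' @return The report tibble, invisibly.
#' @export
write_group_report <- function(references, hypotheses, groups = NULL,
                               path, level = "character") {
  wers <- purrr::map2_dbl(references, hypotheses, wer)
  stats <- group_boxplot_stats(wers, groups)
  dist <- error_distribution(references, hypotheses, level = level,
                             groups = groups)
  report <- dplyr::left_join(
    dplyr::select(stats, "group", "n", "median", "q1", "q3"),
    dplyr::select(dist, "group", "insertion_pct", "substitution_pct",
                  "deletion_pct"),
    by = "group"
  )
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(report)
}
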