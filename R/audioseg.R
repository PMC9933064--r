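#' Mono audio signal container
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `"audio_signal"` with fields `samples`,
#'   `sample_rate` and `duration_s`.
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0 || !all(is.finite(samples))) {
    abort("audio must be non-empty with finite samples",
          class = "curasr_invalid_audio")
  }
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  structure(
    list(samples = samples, sample_rate = as.integer(sample_rate),
         duration_s = length(samples) / sample_rate),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %.3f s @ %d Hz (%d samples)\n",
              x$duration_s, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Silence-based segmenter configuration
#'
#' Controls the recursive silence splitter. Defaults follow the curation
#' recipe: segments must stay below 20 s, silence splitting starts at a
#' 250 ms minimum silence length and halves it until everything fits,
#' bottoming out at `silence_floor_ms`. A frame is silent when its RMS
#' energy is below `silence_threshold_dbfs` (dB relative to full scale).
#'
#' @param max_segment_s Upper bound on segment duration (s). Default 20.
#' @param initial_min_silence_ms First-pass minimum silence length (ms).
#'   Default 250.
#' @param silence_floor_ms Smallest minimum-silence length tried before
#'   force-splitting (ms). Default 15.
#' @param silence_threshold_dbfs Frame-RMS silence threshold (dBFS).
#'   Default -40.
#' @param frame_ms,hop_ms Analysis frame length and hop (ms). Defaults 25/10.
#' @param min_segment_s Segments shorter than this are merged with a
#'   neighbour when possible (s). Default 1.
#' @return A list of class `"segmenter_config"`.
#' @export
segmenter_config <- function(max_segment_s = 20, initial_min_silence_ms = 250,
                             silence_floor_ms = 15,
                             silence_threshold_dbfs = -40,
                             frame_ms = 25, hop_ms = 10, min_segment_s = 1) {
  stopifnot(max_segment_s > min_segment_s, min_segment_s > 0,
            initial_min_silence_ms > silence_floor_ms, silence_floor_ms > 0,
            frame_ms > 0, hop_ms > 0, hop_ms <= frame_ms)
  structure(
    list(max_segment_s = max_segment_s,
         initial_min_silence_ms = initial_min_silence_ms,
         silence_floor_ms = silence_floor_ms,
         silence_threshold_dbfs = silence_threshold_dbfs,
         frame_ms = frame_ms, hop_ms = hop_ms, min_segment_s = min_segment_s),
    class = "segmenter_config"
  )
}

# Frame RMS in dBFS on the hop grid. Cumulative sum of squares keeps long
# recordings cheap. Returns tibble(frame, start_s, end_s, rms_dbfs).
frame_energies <- function(audio, config) {
  stopifnot(inherits(audio, "audio_signal"))
  n <- length(audio$samples)
  frame_n <- max(1L, round(config$frame_ms / 1000 * audio$sample_rate))
  hop_n <- max(1L, round(config$hop_ms / 1000 * audio$sample_rate))
  starts <- seq(1L, max(1L, n - frame_n + 1L), by = hop_n)
  cs <- c(0, cumsum(audio$samples^2))
  ends <- pmin(starts + frame_n - 1L, n)
  ms <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  tibble(
    frame = seq_along(starts),
    start_s = (starts - 1L) / audio$sample_rate,
    end_s = ends / audio$sample_rate,
    rms_dbfs = 10 * log10(pmax(ms, 1e-12))
  )
}

# Runs of TRUE in a logical vector -> tibble(first, last) of indices.
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(first = starts[r$values], last = ends[r$values])
}

#' Detect silences in a recording
#'
#' Returns maximal, non-overlapping, time-ordered spans in which every
#' analysis frame has RMS energy below the silence threshold and whose
#' duration is at least `min_silence_ms`. Spans are half-open
#' `[start_s, end_s)` and snapped to the hop grid.
#'
#' @param audio An [audio_signal()].
#' @param config A [segmenter_config()].
#' @param min_silence_ms Minimum silence duration (ms); defaults to the
#'   config's first-pass value.
#' @return A tibble with columns `start_s`, `end_s`, `duration_s`.
#' @export
detect_silences <- function(audio, config = segmenter_config(),
                            min_silence_ms = config$initial_min_silence_ms) {
  stopifnot(min_silence_ms >= config$silence_floor_ms)
  fe <- frame_energies(audio, config)
  runs <- .runs(fe$rms_dbfs < config$silence_threshold_dbfs)
  out <- tibble(
    start_s = fe$start_s[runs$first],
    end_s = fe$end_s[runs$last]
  )
  out$duration_s <- out$end_s - out$start_s
  out[out$duration_s >= min_silence_ms / 1000, , drop = FALSE]
}

#' Split a recording at silences, recursively halving the minimum silence
#'
#' Cuts a long recording into voiced segments: first at silences of at
#' least `initial_min_silence_ms`; any resulting segment longer than
#' `max_segment_s` is re-split with the minimum silence length halved, and
#' so on until all segments fit. If the minimum would fall below
#' `silence_floor_ms` and a segment is still too long, it is force-split at
#' its lowest-energy interior frame (never mid-frame). Cut points fall
#' inside silences and every segment is trimmed to its voiced extent, so
#' returned spans exclude the splitting silences entirely and their union
#' covers all frames classified voiced. Finally, segments shorter than
#' `min_segment_s` are merged with the shorter adjacent neighbour when the
#' merge stays within `max_segment_s`.
#'
#' @inheritParams detect_silences
#' @return A tibble of ordered, disjoint spans: `start_s`, `end_s`,
#'   `duration_s`.
#' @export
split_recursive <- function(audio, config = segmenter_config()) {
  fe <- frame_energies(audio, config)
  voiced <- fe$rms_dbfs >= config$silence_threshold_dbfs
  if (!any(voiced)) {
    return(tibble(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0)))
  }

  seg_duration <- function(first, last) fe$end_s[last] - fe$start_s[first]

  # Duration of the silent run between voiced frames `last` and `first`,
  # on the same span convention as detect_silences().
  gap_duration <- function(prev_last, next_first) {
    if (next_first - prev_last < 2) return(0)
    fe$end_s[next_first - 1L] - fe$start_s[prev_last + 1L]
  }

  # Group voiced frame-runs within frames first..last: runs separated by a
  # silent gap >= min_sil_s fall into different segments.
  group_at <- function(first, last, min_sil_s) {
    isl <- .runs(voiced[first:last])
    isl$first <- isl$first + first - 1L
    isl$last <- isl$last + first - 1L
    if (nrow(isl) < 2) return(isl)
    gaps <- vapply(seq_len(nrow(isl) - 1), function(k) {
      gap_duration(isl$last[k], isl$first[k + 1])
    }, numeric(1))
    grp <- cumsum(c(0L, as.integer(gaps >= min_sil_s)))
    tibble(first = as.integer(tapply(isl$first, grp, min)),
           last = as.integer(tapply(isl$last, grp, max)))
  }

  force_split <- function(first, last) {
    if (seg_duration(first, last) <= config$max_segment_s ||
        last - first < 2) {
      return(tibble(first = first, last = last))
    }
    inner <- (first + 1L):(last - 1L)
    cut <- inner[which.min(fe$rms_dbfs[inner])]
    dplyr::bind_rows(force_split(first, cut - 1L), force_split(cut, last))
  }

  split_span <- function(first, last, min_sil_ms) {
    if (seg_duration(first, last) <= config$max_segment_s) {
      return(tibble(first = first, last = last))
    }
    if (min_sil_ms < config$silence_floor_ms) {
      return(force_split(first, last))
    }
    grouped <- group_at(first, last, min_sil_ms / 1000)
    if (nrow(grouped) == 1) {
      return(split_span(first, last, min_sil_ms / 2))
    }
    purrr::pmap(grouped, function(first, last) {
      split_span(first, last, min_sil_ms / 2)
    }) |> dplyr::bind_rows()
  }

  top <- group_at(1L, nrow(fe), config$initial_min_silence_ms / 1000)
  segs <- purrr::pmap(top, function(first, last) {
    split_span(first, last, config$initial_min_silence_ms / 2)
  }) |> dplyr::bind_rows()
  segs <- segs[order(segs$first), , drop = FALSE]

  out <- tibble(start_s = fe$start_s[segs$first], end_s = fe$end_s[segs$last])
  out <- .merge_short(out, config)
  out$duration_s <- out$end_s - out$start_s
  out
}

# Merge segments shorter than min_segment_s into the shorter adjacent
# neighbour, provided the merged span stays within max_segment_s.
.merge_short <- function(out, config) {
  blocked <- rep(FALSE, nrow(out))
  repeat {
    if (nrow(out) < 2) break
    dur <- out$end_s - out$start_s
    short <- which(dur < config$min_segment_s & !blocked)
    if (length(short) == 0) break
    i <- short[1]
    cands <- c(if (i > 1) i - 1L, if (i < nrow(out)) i + 1L)
    if (length(cands) == 2 && dur[i + 1] < dur[i - 1]) cands <- rev(cands)
    merged <- FALSE
    for (j in cands) {
      s <- min(out$start_s[i], out$start_s[j])
      e <- max(out$end_s[i], out$end_s[j])
      if (e - s <= config$max_segment_s) {
        keep <- min(i, j)
        out$start_s[keep] <- s
        out$end_s[keep] <- e
        out <- out[-max(i, j), , drop = FALSE]
        blocked <- rep(FALSE, nrow(out))
        merged <- TRUE
        break
      }
    }
    if (!merged) blocked[i] <- TRUE
  }
  out
}

#' Extract the audio of a time span
#'
#' @param audio An [audio_signal()].
#' @param start_s,end_s Half-open span in seconds.
#' @return An [audio_signal()] containing the span's samples.
#' @export
slice_audio <- function(audio, start_s, end_s) {
  stopifnot(inherits(audio, "audio_signal"),
            start_s >= 0, end_s > start_s,
            end_s <= audio$duration_s + 1 / audio$sample_rate)
  i0 <- floor(start_s * audio$sample_rate) + 1L
  i1 <- min(length(audio$samples), ceiling(end_s * audio$sample_rate))
  audio_signal(audio$samples[i0:i1], audio$sample_rate)
}
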