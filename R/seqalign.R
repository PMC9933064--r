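#' Smith-Waterman scoring scheme
#'
#' Classic local-alignment scoring over word tokens. Token equality is exact
#' string equality after normalization; there is no fuzzy word matching.
#'
#' @param match Score for a token match; must be positive. Default 2.
#' @param mismatch Score for a token mismatch; must be non-positive. Default -1.
#' @param gap Score for a gap on either side; must be non-positive. Default -1.
#' @return A list of class `"sw_scoring"`.
#' @export
sw_scoring <- function(match = 2, mismatch = -1, gap = -1) {
  if (!(is.numeric(match) && match > 0)) {
    abort("`match` must be a positive number", class = "curasr_bad_scoring")
  }
  if (!(is.numeric(mismatch) && mismatch <= 0)) {
    abort("`mismatch` must be non-positive", class = "curasr_bad_scoring")
  }
  if (!(is.numeric(gap) && gap <= 0)) {
    abort("`gap` must be non-positive", class = "curasr_bad_scoring")
  }
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "sw_scoring")
}

.OP_LEVELS <- c("match", "mismatch", "gap_in_query", "gap_in_ref")

#' Local alignment of a hypothesis inside a long reference transcript
#'
#' Finds the maximal-scoring local alignment of a (short) query token
#' sequence against a (long) reference token sequence under the classic
#' Smith-Waterman recurrence with linear gap costs. This is how a segment's
#' ASR hypothesis is located inside the full-length manual transcript; the
#' matched reference slice later serves as the corrected label.
#'
#' Determinism: among equal-scoring end cells the smallest reference end
#' index wins (then the smallest query end index); during traceback
#' match/mismatch is preferred over `gap_in_ref` over `gap_in_query`.
#'
#' The similarity attached to the alignment is the number of matched tokens
#' divided by the full query token count (not the span length): it is 1
#' exactly when every hypothesised word appears, in order, in the reference.
#' An empty query or reference yields score 0, empty spans and similarity 0.
#'
#' @param query Character vector of (normalized) hypothesis tokens.
#' @param reference Character vector of (normalized) reference tokens.
#' @param scoring A [sw_scoring()].
#' @return An object of class `"local_alignment"`: a list with `score`,
#'   `similarity`, `n_matches`, half-open token spans `query_span` and
#'   `ref_span` (1-based start, exclusive end), and `ops`, a factor over
#'   match / mismatch / gap_in_query / gap_in_ref. `gap_in_query` ops consume
#'   a query token (a hypothesis word with no reference counterpart);
#'   `gap_in_ref` ops consume a reference token.
#' @examples
#' smith_waterman(c("the", "cat", "sat"),
#'                c("a", "dog", "and", "the", "cat", "sat", "down"))
#' @export
smith_waterman <- function(query, reference, scoring = sw_scoring()) {
  stopifnot(inherits(scoring, "sw_scoring"))
  query <- as.character(query)
  reference <- as.character(reference)
  if (length(query) == 0 || length(reference) == 0) {
    res <- list(score = 0, q_start = 0L, q_end = 0L, r_start = 0L,
                r_end = 0L, ops = integer(0))
  } else {
    res <- sw_align_cpp(query, reference,
                        scoring$match, scoring$mismatch, scoring$gap)
  }
  ops <- factor(.OP_LEVELS[res$ops + 1L], levels = .OP_LEVELS)
  n_matches <- sum(ops == "match")
  structure(
    list(
      score = res$score,
      similarity = if (length(query) == 0) 0 else n_matches / length(query),
      n_matches = n_matches,
      query_length = length(query),
      query_span = c(start = res$q_start + 1L, end = res$q_end + 1L),
      ref_span = c(start = res$r_start + 1L, end = res$r_end + 1L),
      ops = ops,
      scoring = scoring
    ),
    class = "local_alignment"
  )
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("<local_alignment> score", format(x$score),
      " similarity", sprintf("%.3f", x$similarity), "\n")
  cat("  query span [", x$query_span[["start"]], ",", x$query_span[["end"]],
      ")  ref span [", x$ref_span[["start"]], ",", x$ref_span[["end"]],
      ")\n", sep = "")
  invisible(x)
}

#' @describeIn smith_waterman One row per alignment operation, with the
#'   1-based query/reference token index each op consumes (NA for gaps).
#' @param x A `local_alignment`.
#' @param ... Unused.
#' @export
tidy.local_alignment <- function(x, ...) {
  qi <- x$query_span[["start"]]
  ri <- x$ref_span[["start"]]
  q_idx <- r_idx <- rep(NA_integer_, length(x$ops))
  for (k in seq_along(x$ops)) {
    op <- as.character(x$ops[k])
    if (op %in% c("match", "mismatch", "gap_in_query")) {
      q_idx[k] <- qi; qi <- qi + 1L
    }
    if (op %in% c("match", "mismatch", "gap_in_ref")) {
      r_idx[k] <- ri; ri <- ri + 1L
    }
  }
  tibble(op = x$ops, query_index = q_idx, ref_index = r_idx)
}

#' @describeIn smith_waterman One-row summary (score, similarity, spans).
#' @export
glance.local_alignment <- function(x, ...) {
  tibble(
    score = x$score, similarity = x$similarity, n_matches = x$n_matches,
    query_length = x$query_length,
    query_start = x$query_span[["start"]], query_end = x$query_span[["end"]],
    ref_start = x$ref_span[["start"]], ref_end = x$ref_span[["end"]]
  )
}

#' Similarity gate for curated segments
#'
#' Accepts an alignment when its similarity reaches the threshold; a
#' similarity strictly below the threshold is discarded. The default
#' threshold of 0.90 corresponds to discarding segments whose hypothesis
#' shares fewer than 90% of its words with the best-matching transcript
#' slice.
#'
#' @param alignment A `local_alignment` (or a bare similarity in `[0, 1]`).
#' @param threshold Acceptance threshold in `[0, 1]`. Default 0.90.
#' @return `TRUE` (accept) or `FALSE` (discard).
#' @export
gate_alignment <- function(alignment, threshold = 0.9) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  sim <- if (inherits(alignment, "local_alignment")) {
    alignment$similarity
  } else {
    as.numeric(alignment)
  }
  sim >= threshold
}

#' Extract the corrected text for an aligned segment
#'
#' Returns the reference tokens covered by the alignment's reference span:
#' the transcript slice adopted as the training label (the correction) for
#' the audio segment whose hypothesis was aligned.
#'
#' @param alignment A `local_alignment` produced against `reference`.
#' @param reference The same reference token vector the alignment used.
#' @return A character vector of reference tokens (empty for an empty
#'   alignment).
#' @export
extract_correction <- function(alignment, reference) {
  stopifnot(inherits(alignment, "local_alignment"))
  s <- alignment$ref_span[["start"]]
  e <- alignment$ref_span[["end"]]
  if (e <= s) return(character(0))
  if (s < 1 || e - 1 > length(reference)) {
    abort("alignment reference span exceeds reference bounds",
          class = "curasr_span_out_of_bounds")
  }
  reference[s:(e - 1L)]
}
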