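.as_tokens <- function(x) {
  if (length(x) == 1 && (is.na(x) || grepl("\\s", x))) {
    x <- normalize_text(x)
  }
  as.character(x)
}

.units_for_level <- function(tokens, level) {
  if (level == "character") to_characters(tokens) else tokens
}

#' Edit-operation counts between a reference and a hypothesis
#'
#' Counts hits, substitutions, insertions and deletions under a minimal-cost
#' Levenshtein alignment with unit costs, at word or character level. At
#' character level the unit sequence is the space-joined character rendering
#' from [to_characters()], so word boundaries count as characters — the
#' convention used for character-level error analyses of ASR output.
#' Among equal-cost paths the traceback maximises hits — it prefers a
#' matching diagonal, then deletion, then insertion, then substitution — so
#' the counts are deterministic and a deletion/insertion pair straddling a
#' matched word is not collapsed into two substitutions of equal cost.
#'
#' The counts satisfy `hits + substitutions + deletions == reference length`
#' and `hits + substitutions + insertions == hypothesis length`.
#'
#' @param reference,hypothesis Character vectors of normalized tokens (a
#'   single string containing whitespace is tokenized with [normalize_text()]
#'   first).
#' @param level `"word"` or `"character"`.
#' @return A one-row tibble with columns `level`, `hits`, `substitutions`,
#'   `insertions`, `deletions`, `reference_length`, `hypothesis_length`.
#' @examples
#' edit_ops(c("the", "cat"), c("the", "hat"))
#' @export
edit_ops <- function(reference, hypothesis, level = c("word", "character")) {
  level <- match.arg(level)
  ref <- .units_for_level(.as_tokens(reference), level)
  hyp <- .units_for_level(.as_tokens(hypothesis), level)
  counts <- edit_ops_cpp(ref, hyp)
  tibble(
    level = level,
    hits = counts[["hits"]],
    substitutions = counts[["substitutions"]],
    insertions = counts[["insertions"]],
    deletions = counts[["deletions"]],
    reference_length = length(ref),
    hypothesis_length = length(hyp)
  )
}

#' Word error rate
#'
#' `(substitutions + insertions + deletions) / reference length * 100`, the
#' standard ASR accuracy measure. The denominator is the reference length,
#' so WER can exceed 100% when insertions dominate.
#'
#' @inheritParams edit_ops
#' @return WER as a percentage.
#' @examples
#' wer(c("a", "b", "c"), c("a", "x", "c"))
#' @export
wer <- function(reference, hypothesis) {
  ref <- .as_tokens(reference)
  if (length(ref) == 0) {
    abort("WER is undefined for an empty reference", class = "curasr_empty_ref")
  }
  e <- edit_ops(ref, hypothesis, level = "word")
  (e$substitutions + e$insertions + e$deletions) / e$reference_length * 100
}

#' Pooled corpus word error rate
#'
#' Total edit errors over total reference words across many pairs — the
#' standard corpus-level WER used for validation-set tracking (not the mean
#' of per-pair WERs).
#'
#' @param references,hypotheses Lists of token vectors (parallel).
#' @return WER as a percentage.
#' @export
corpus_wer <- function(references, hypotheses) {
  stopifnot(length(references) == length(hypotheses), length(references) > 0)
  counts <- purrr::map2(references, hypotheses,
                        function(r, h) edit_ops(r, h, level = "word"))
  counts <- dplyr::bind_rows(counts)
  n_ref <- sum(counts$reference_length)
  if (n_ref == 0) {
    abort("WER is undefined for an empty reference", class = "curasr_empty_ref")
  }
  sum(counts$substitutions + counts$insertions + counts$deletions) / n_ref * 100
}

#' Distribution of error types, pooled per group
#'
#' For each speaker group, pools insertion/deletion/substitution counts over
#' all reference/hypothesis pairs and expresses each type as a percentage of
#' the total error count. This is the ratio-of-error-types summary commonly
#' reported per speaker group in ASR error analyses.
#'
#' @param references,hypotheses Lists of token vectors (parallel).
#' @param level `"word"` or `"character"`.
#' @param groups Optional vector of group labels, one per pair; `NULL` pools
#'   everything into one group labelled `"all"`.
#' @return A tibble with one row per group: `group`, `n_pairs`, pooled
#'   `insertions`, `substitutions`, `deletions`, `total_errors`, the three
#'   `*_pct` shares (summing to 100 when any errors exist, all zero with
#'   `zero_errors = TRUE` otherwise).
#' @export
error_distribution <- function(references, hypotheses,
                               level = c("word", "character"),
                               groups = NULL) {
  level <- match.arg(level)
  stopifnot(length(references) == length(hypotheses), length(references) > 0)
  if (is.null(groups)) groups <- rep("all", length(references))
  stopifnot(length(groups) == length(references))
  if (all(purrr::map_int(references, length) == 0)) {
    abort("at least one pair must have a non-empty reference",
          class = "curasr_empty_ref")
  }
  counts <- purrr::map2(references, hypotheses,
                        function(r, h) edit_ops(r, h, level = level))
  counts <- dplyr::bind_rows(counts)
  counts$group <- as.character(groups)
  counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      insertions = sum(.data$insertions),
      substitutions = sum(.data$substitutions),
      deletions = sum(.data$deletions),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total_errors = .data$insertions + .data$substitutions + .data$deletions,
      zero_errors = .data$total_errors == 0,
      insertion_pct = ifelse(.data$zero_errors, 0,
                             100 * .data$insertions / .data$total_errors),
      substitution_pct = ifelse(.data$zero_errors, 0,
                                100 * .data$substitutions / .data$total_errors),
      deletion_pct = ifelse(.data$zero_errors, 0,
                            100 * .data$deletions / .data$total_errors)
    )
}

#' Boxplot statistics of WER values per speaker group
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); outliers are values outside
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]`.
#'
#' @param wer_values Numeric WER percentages.
#' @param groups Group label per value; `NULL` for a single `"all"` group.
#' @return A tibble with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `iqr`, and `outliers` (a list column of values beyond the
#'   whiskers).
#' @export
group_boxplot_stats <- function(wer_values, groups = NULL) {
  stopifnot(is.numeric(wer_values), length(wer_values) > 0)
  if (is.null(groups)) groups <- rep("all", length(wer_values))
  stopifnot(length(groups) == length(wer_values))
  if (anyNA(wer_values) || anyNA(groups)) {
    abort("WER values and groups must not contain NA",
          class = "curasr_missing_group")
  }
  tibble(wer = wer_values, group = as.character(groups)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$wer),
      q1 = quantile(.data$wer, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$wer, 0.75, type = 7, names = FALSE),
      iqr = q3 - q1,
      outliers = list(.data$wer[.data$wer < q1 - 1.5 * (q3 - q1) |
                                .data$wer > q3 + 1.5 * (q3 - q1)]),
      .groups = "drop"
    )
}
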