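#' Text normalization configuration
#'
#' The restricted character vocabulary used throughout the pipeline: the 26
#' basic Latin letters, the space, the ASCII hyphen and the ASCII apostrophe.
#' Raw transcripts and ASR hypotheses are mapped onto this vocabulary before
#' any alignment or error computation, mirroring acoustic models whose output
#' alphabet is letters plus dash and apostrophe, with accent marks removed.
#'
#' @param strip_accents Map accented letters to their unaccented base letter
#'   (canonical decomposition, then removal of combining marks). Default `TRUE`.
#' @param case_fold Fold to lower case. Case carries no information for word
#'   error rates, so folding is on by default.
#' @param digit_policy What to do with decimal digits, which the restricted
#'   vocabulary does not contain: `"drop"` (replace by space, with a warning
#'   when digits are present) or `"keep_verbatim"`.
#' @return A list of class `"norm_config"`.
#' @examples
#' normalize_text("Hé, ömdat!", norm_config())
#' @export
norm_config <- function(strip_accents = TRUE, case_fold = TRUE,
                        digit_policy = c("drop", "keep_verbatim")) {
  digit_policy <- match.arg(digit_policy)
  structure(
    list(
      keep_characters = c(letters, " ", "-", "'"),
      strip_accents = isTRUE(strip_accents),
      case_fold = isTRUE(case_fold),
      digit_policy = digit_policy
    ),
    class = "norm_config"
  )
}

#' Normalize raw text onto the restricted character vocabulary
#'
#' Maps arbitrary Unicode text to a token sequence over the allowed alphabet
#' (letters, hyphen, apostrophe). Typographic apostrophes become ASCII `'`;
#' em and en dashes become spaces (in transcripts they mark pauses, not
#' compound words), while the intra-word ASCII hyphen is kept; accented
#' letters lose their marks; every other disallowed character becomes a
#' space; runs of whitespace collapse. Tokens without any letter are dropped.
#' Normalization is idempotent: normalizing the rendering of a normalized
#' text reproduces it exactly.
#'
#' @param raw_text A character scalar (may be empty) or a vector, which is
#'   treated as already-split text and joined by spaces first.
#' @param config A [norm_config()].
#' @return A character vector of word tokens (possibly empty).
#' @examples
#' normalize_text("the last—is there something you want to tell")
#' @export
normalize_text <- function(raw_text, config = norm_config()) {
  stopifnot(inherits(config, "norm_config"))
  x <- paste(as.character(raw_text), collapse = " ")
  if (is.na(x) || x == "") return(character(0))

  # apostrophe dialects and dash dialects first, while still Unicode
  x <- stringi::stri_replace_all_regex(x, "[’‘ʼ`´]", "'")
  x <- stringi::stri_replace_all_regex(x, "[–—―]", " ")

  if (config$case_fold) x <- stringi::stri_trans_tolower(x)
  if (config$strip_accents) {
    x <- stringi::stri_trans_nfd(x)
    x <- stringi::stri_replace_all_regex(x, "\\p{Mn}", "")
  }
  if (config$digit_policy == "drop") {
    if (stringi::stri_detect_regex(x, "[0-9]")) {
      warn("digits present in input were dropped (digit_policy = \"drop\")",
           class = "curasr_digits_dropped")
    }
    x <- stringi::stri_replace_all_regex(x, "[0-9]", " ")
  }

  allowed <- setdiff(config$keep_characters, " ")
  allowed <- c(setdiff(allowed, "-"), if ("-" %in% allowed) "-")  # "-" literal at class end
  keep <- paste0(
    "[^\\s", if (config$digit_policy == "keep_verbatim") "0-9",
    paste0(allowed, collapse = ""), "]"
  )
  x <- stringi::stri_replace_all_regex(x, keep, " ")
  tokens <- stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)[[1]]
  # a token must contain at least one letter (or digit under keep_verbatim):
  # bare runs of hyphens/apostrophes are punctuation, not words
  has_core <- stringi::stri_detect_regex(tokens, "[a-z0-9]")
  tokens[has_core]
}

#' Render a token sequence as a single string
#'
#' @param tokens A character vector of word tokens.
#' @return The space-joined character rendering (empty string for no tokens).
#' @export
render_text <- function(tokens) {
  if (length(tokens) == 0) return("")
  paste(tokens, collapse = " ")
}

#' Character sequence of a token list
#'
#' Joins tokens with single spaces and splits into individual characters;
#' this is the unit sequence for character-level error analysis.
#'
#' @param tokens A character vector of word tokens.
#' @return A character vector of single characters (empty for no tokens).
#' @examples
#' to_characters(c("ab", "c"))
#' @export
to_characters <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  strsplit(render_text(tokens), "", fixed = TRUE)[[1]]
}
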