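Package: curasr
Title: Iterative Curation of Speech-Recognition Corpora from Long
    Recordings and Untimed Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns long interview recordings with full-length, untimed
    manual transcripts into curated short audio/text training pairs for
    automatic speech recognition (ASR). Recordings are split at detected
    silences with a recursively halved minimum-silence length until every
    segment fits a length bound; per-segment ASR hypotheses are locally
    aligned to the manual transcript with the Smith-Waterman algorithm; a
    similarity gate discards poor matches and the matched transcript text
    becomes the corrected label. A Noisy-Student-style loop alternates
    curation and backend finetuning until the validation word error rate
    (WER) plateaus. Includes WER with insertion/deletion/substitution
    decomposition at word and character level, per-group error
    distributions and boxplot statistics, a synthetic-interview generator
    with planted silences and controllable corruption rates, a pluggable
    (mock) ASR backend contract, WAV and JSONL manifest I/O, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    stringi,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
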