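# curasr

Iterative curation of automatic-speech-recognition (ASR) training corpora
from long recordings and full-length, untimed manual transcripts.

## The problem

Qualitative health research — interviews with care-home residents, family
members and care professionals, for example — produces exactly the data an
ASR system for that population needs, but in the wrong shape: hour-long
recordings paired with one long verbatim transcript carrying no
timestamps. Acoustic models train on short (< 20 s) audio segments with
exact text labels. curasr turns the former into the latter, for speech
scientists and health-informatics teams who want to adapt an ASR model to
a population its training data under-represents (older adults, strong
accents, impaired speech).

## The method

A Noisy-Student-style curation loop:

1. **Segment.** Split each recording at silences: frames (25 ms, 10 ms
   hop) with RMS energy below −40 dBFS are silent; silences ≥ 250 ms cut
   the recording. Any segment still longer than 20 s is re-split with the
   minimum silence length halved, recursively, until all segments fit.
2. **Transcribe** each segment *S* with the current model, giving a
   hypothesis *P*.
3. **Align** *P* against the full manual transcript with the
   Smith–Waterman local-alignment recurrence on word tokens
   (match +2, mismatch −1, gap −1):
   `H(i,j) = max{0, H(i−1,j−1) + s(qᵢ, rⱼ), H(i−1,j) − 1, H(i,j−1) − 1}`.
4. **Gate.** Similarity = matched tokens / |*P*|. If similarity < p
   (default 0.90) the segment is discarded; otherwise the matched
   transcript slice becomes the correction *P′*.
5. **Finetune** the model on all accepted (*S*, *P′*) pairs, measure word
   error rate `WER = (S + I + D) / N_ref × 100` on a fixed validation set,
   and repeat until the WER no longer decreases.

The package implements all of this with a pluggable backend contract
(mock/oracle backends included; real neural backends attach via
`asr_backend()`), word- and character-level edit-operation decomposition
(insertions / deletions / substitutions), per-speaker-group error
distributions and boxplot statistics, WAV and JSONL-manifest I/O, a
synthetic-interview generator with planted silences and controllable
corruption rates, and a small CLI (`inst/cli/curasr`).

## A worked example

The gate in action on a segment hypothesis whose transcript counterpart
dropped a word ("question") and differs in another ("something" vs
"anything"):

```r
library(curasr)
hyp <- normalize_text("fthe last question is there anything you want to tell")
ref <- normalize_text("the last—is there something you want to tell")
aln <- smith_waterman(hyp, ref)
glance(aln)
#> # A tibble: 1 × 8
#>   score similarity n_matches query_length query_start query_end ref_start
#>   <dbl>      <dbl>     <int>        <int>       <int>     <int>     <int>
#> 1    12        0.7         7           10           2        11         2
gate_alignment(aln, 0.90)
#> [1] FALSE
wer(ref, hyp)
#> [1] 33.33333
```

Seven of the ten hypothesis words match the transcript in order, so the
similarity is 0.70 — below the 0.90 gate, and the segment is discarded
rather than paired with a wrong label. Its word-level WER against the
transcript is 33.3% (2 substitutions + 1 insertion over 9 reference
words).

The full loop on synthetic interviews, with a mock backend that starts at
a 30% word error rate and halves it at each finetune:

```r
ivs <- list(iv1 = generate_interview(synth_spec(seed = 101)),
            iv2 = generate_interview(synth_spec(seed = 102)),
            val = generate_interview(synth_spec(n_utterances = 20,
                     words_per_utterance = c(15, 25), seed = 199)))
backend <- mock_backend(ivs, word_error_rate = 0.3,
                        improvement_factor = 0.5, seed = 7)
run <- curate_iterate(backend, ivs[1:2],
                      validation_from_interview(ivs$val, "val"))
run
#> <curation_run> 7 recorded iterations; stop: wer_increased
#> # A tibble: 7 × 3
#>   iteration cumulative_accepted_samples validation_wer_pct
#>       <int>                       <int>              <dbl>
#> 1         0                           0             28
#> 2         1                          11             11.7
#> 3         2                          18              6.67
#> 4         3                          21              4.8
#> 5         4                          24              1.87
#> 6         5                          24              0.533
#> 7         6                          24              0.8
```

Validation WER falls while the cumulative accepted-sample count grows,
then the loop stops when WER stops improving (restoring the best backend
state). `tidy(run)`, `glance(run)` and `autoplot(run)` expose the history;
`write_manifest()` / `write_iteration_log()` persist it.

## Vignette

`vignettes/curating-asr-corpora.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
numerical conventions (similarity definition, Levenshtein tie-break,
quartile convention, stopping rule), what the synthetic generator does and
does not emulate, and known limitations.
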