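---
title: "Curating ASR training corpora from long recordings and untimed transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating ASR training corpora from long recordings and untimed transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Interview studies in long-term care (and qualitative health research
generally) accumulate hours of recorded speech together with full-length
verbatim transcripts that carry no timestamps. That combination is almost,
but not quite, an ASR training corpus: acoustic models need short audio
segments paired with their exact text, while the data at hand are hour-long
recordings paired with one long text. curasr closes that gap with a
curation loop:

1. **Segment** each recording at detected silences, so cuts fall between
   utterances rather than mid-word, and no segment exceeds the length an
   acoustic model can consume (20 s by default).
2. **Transcribe** each segment with the current ASR backend, giving a
   hypothesis.
3. **Locate** the hypothesis inside the full manual transcript by
   Smith–Waterman local alignment on word tokens.
4. **Gate** on alignment similarity: segments whose hypothesis shares at
   least 90% of its words (by default) with the best-matching transcript
   slice are kept, and that slice — the human transcription — becomes the
   segment's corrected label. Poor matches are discarded rather than
   risking a wrong-location label.
5. **Finetune** the backend on all accepted pairs, re-measure word error
   rate (WER) on a fixed validation set, and repeat from step 2 until the
   WER stops improving.

This is a Noisy-Student-style scheme in which the "student's" pseudo-labels
are corrected by the manual transcript before retraining. The package
implements every stage, a pluggable backend contract with seeded mock
backends, the WER/error-decomposition metrics used to monitor the loop, and
a synthetic-interview generator so the whole pipeline is testable without
any private interview data.

```{r, eval = FALSE}
library(curasr)
iv  <- generate_interview(synth_spec(seed = 1))
be  <- mock_backend(list(iv = iv), word_error_rate = 0.3)
curate_pass(be, iv$audio, iv$transcript, audio_id = "iv")
```

## Text normalization

All alignment and error computation happens over a restricted vocabulary:
the 26 basic Latin letters, space, hyphen and apostrophe — the output
alphabet of character-level acoustic models trained without accent marks.
`normalize_text()` case-folds, strips accents by canonical decomposition
followed by removal of combining marks (so no lookup table is needed), maps
typographic apostrophes to `'`, and replaces every other character with a
space before tokenizing.

Choices worth stating explicitly:

* **Case** is folded to lower case: case carries no information for WER and
  folding simplifies equality testing.
* **Em/en dashes** become spaces, not hyphens: in verbatim transcripts they
  mark pauses, not compound words. The intra-word ASCII hyphen is kept.
* **Digits** are dropped (with a warning) by default because the restricted
  vocabulary has no digits and no verbalization rule is defined;
  `digit_policy = "keep_verbatim"` retains them. How numerals in real
  manual transcripts should be verbalized is an open question we
  deliberately do not guess at — verbalization is out of scope.
* Normalization is **idempotent**: normalizing the rendering of a
  normalized text reproduces it exactly. The test suite checks this as a
  property over random Unicode input.

## Local alignment and the similarity gate

`smith_waterman()` runs the classic local-alignment recurrence with linear
gap costs on **word tokens**, not characters: the gate's job is to protect
against wrong-location matches, and word identity is the robust, fast
signal for that on long transcripts. Defaults are match +2, mismatch −1,
gap −1 — a standard parameterization, exposed via `sw_scoring()`. Full
O(|query|·|reference|) dynamic programming is acceptable because queries
are hypotheses of under-20 s segments (tens of tokens), and it runs in
compiled code.

**Similarity** is defined as the number of matched tokens divided by the
full query token count. It is 1 exactly when every hypothesised word
appears, in order, in the reference — the natural reading of "the
hypothesis and the transcript say the same thing" — and it penalises both
hypothesis words with no transcript counterpart and words the aligner had
to mismatch. Whether the 90% gate of the original recipe was token- or
character-based is not documented anywhere we know of; token-based is this
package's choice and the threshold is a plain argument.

The gate **accepts at the threshold** (similarity ≥ p) and discards
strictly below it. Determinism is pinned by explicit tie-breaks: among
equal-scoring end cells the smallest reference end index wins, and the
traceback prefers match/mismatch over a reference gap over a query gap.
Token equality is exact string equality after normalization; there is no
fuzzy word matching.

## Silence-based segmentation

No segmentation method is canonical for this task, so the package uses the
simplest reproducible detector: frame RMS energy against a fixed threshold.

| parameter | default | meaning |
|---|---|---|
| `frame_ms` / `hop_ms` | 25 / 10 ms | analysis frame and hop |
| `silence_threshold_dbfs` | −40 dBFS | frame is silent below this RMS |
| `initial_min_silence_ms` | 250 ms | first-pass minimum silence |
| `max_segment_s` | 20 s | hard upper bound on segment length |
| `min_segment_s` | 1 s | segments shorter than this merge |
| `silence_floor_ms` | 15 ms | smallest minimum silence tried |

`split_recursive()` first cuts at silences of at least 250 ms; any segment
still longer than 20 s is re-split with the minimum silence halved (125,
62.5, ... ms) until everything fits. Conceptually each cut falls at the
midpoint of a silence; because every segment is then trimmed to its voiced
extent, the returned spans simply exclude splitting silences entirely, and
their union covers exactly the frames classified voiced. If the minimum
silence would drop below `silence_floor_ms` and a segment is still too
long, it is force-split at its lowest-energy interior frame — never
mid-frame — so the length bound always holds. Segments shorter than
`min_segment_s` are merged into the shorter adjacent neighbour when the
merged span still fits; too-short segments carry too little information to
train on, but a merge is never allowed to violate the 20 s bound.

Boundaries snap to the hop grid, so planted-boundary recovery is accurate
to roughly one frame (±25 ms at defaults); the tests assert ±50 ms. All
audio is converted to one internal format (16 kHz mono, via `read_wav()`)
before analysis. An adaptive threshold (10th percentile of frame energies)
was considered and rejected for the default path: a fixed dBFS threshold
is reproducible across recordings and the config exposes it directly.

## Edit metrics

`edit_ops()` counts hits, substitutions, insertions and deletions under a
minimal-cost unit-weight Levenshtein alignment, at word level or at
character level (where the unit sequence is the space-joined character
rendering, so word boundaries count as characters). The identities
`hits + S + D = |reference|` and `hits + S + I = |hypothesis|` hold by
construction and are property-tested. WER is `(S + I + D) / |reference| ×
100`, with the reference length as denominator — WER can therefore exceed
100% when insertions dominate.

Minimal-cost decompositions are not unique: a deletion plus an insertion
straddling one matched word costs the same as two substitutions. The
traceback therefore maximises hits — it prefers a matching diagonal, then
deletion, then insertion, then substitution. A substitution-first
tie-break was tried and rejected: it systematically converts
deletion/insertion pairs into substitutions and biases the recovered
error-type decomposition by about two percentage points at realistic error
rates, which defeats the decomposition's purpose. With the hit-maximising
rule the only residual bias is real: when the noise process genuinely
deletes a word and inserts another in its place, the minimal-cost reading
*is* one substitution, and the recovered insertion/deletion rates sit about
half a point to a point below the nominal injection rates as a result.

`error_distribution()` pools counts over pairs per speaker group and
reports each type as a share of total errors (shares sum to 100 when any
errors exist; a zero-error group is flagged rather than divided by zero).
`group_boxplot_stats()` pins the quartile convention — linear interpolation
between order statistics (`quantile()` type 7) — and flags values beyond
1.5×IQR whiskers, so boxplot summaries are reproducible to the digit.
Validation WER in the loop is the pooled corpus WER (total errors over
total reference words), not the mean of per-segment WERs; the pooled form
is the standard corpus metric and is insensitive to segment length
imbalance.

## The iteration loop and its stopping rule

`curate_iterate()` records iteration 0 as the initial backend's validation
WER with zero accepted samples, then alternates curation and finetuning.
Design choices where the recipe leaves room:

* **Plateau** is operationalised as `previous − new ≤ epsilon` with
  `epsilon = 0` percentage points by default; a WER increase also stops the
  loop, restoring the previous backend state when the backend supports
  snapshots.
* **Finetuning data** per iteration is all accepted pairs accumulated so
  far, keyed by segment identity so re-accepted segments are not double
  counted; cumulative accepted counts are non-decreasing by construction.
  Previously accepted segments are re-curated each pass with the newest
  backend (freezing them is the other defensible reading; re-curation uses
  strictly more information).
* **Safety cap** `max_iterations = 10`.
* The validation set is fixed across iterations and must be disjoint from
  the curation corpus.

## The synthetic data model — what it does and does not emulate

`generate_interview()` plants utterances (Gaussian-noise or sine bursts at
−20 dBFS RMS) separated by silences of configurable duration over a
−60 dBFS noise floor, records exact boundaries, and concatenates the
per-utterance word sequences into an untimed transcript — exactly the
input contract of the real pipeline. `corrupt_text()` is the noise model
behind `mock_backend()`: per word, one draw decides delete / substitute /
keep, and a vocabulary word is inserted after a position with the insertion
probability; `finetune()` multiplies the backend's total error rate by an
improvement factor.

Deliberate non-realism: the "speech" is an energy pattern, not speech — the
segmenter only ever inspects frame energy, so acoustic realism would add
cost without adding test power. Consequently, passing tests demonstrate
the pipeline's logic (segmentation geometry, alignment, gating, metric
arithmetic, loop control), **not** robustness to reverberation, overlapped
speech, background noise near the silence threshold, or real ASR error
structure, all of which are correlated and burstier than independent
per-word corruption. Speaker characteristics (age, accent) have no
computable definition here and are not modelled. Default generator
settings: 12 utterances of 2–6 s, 5–15 words each, silences 300–800 ms
(comfortably above the 250 ms first-pass minimum), a 200-word Dutch
vocabulary that is stable under normalization.

## Problem sizes and tolerances in the test suite

The suite checks alignment optimality against an exhaustive
substring-enumeration oracle on 220 random instances of up to 8 tokens;
edit identities on 1,000 random pairs; corruption-rate recovery within
±1.5 percentage points on 12,000 words (120 sentences of 100 words, pooled
— pooling many short pairs keeps the quadratic DP cheap and matches how
error distributions are computed on real corpora); boundary recovery
within ±50 ms; and the loop shape (strictly decreasing WER for at least
three iterations, non-decreasing sample counts, plateau stop) with the
mock backend at rate 0.3 and improvement factor 0.5 on three 10-utterance
interviews against a 20-utterance validation interview of 15–25-word
utterances — the validation size is chosen so that binomial noise on the
WER estimate is small relative to the expected per-iteration improvement.
Mock-backend rate recovery is asserted against the analytic expectation of
the noise process (nominal rate minus the deletion×insertion composition
term) rather than the nominal rate itself.

## Known limitations

* Linear (not affine) gap penalties; no character-level fuzzy alignment;
  no lattice/multi-hypothesis alignment.
* The energy-threshold detector will mis-segment recordings whose noise
  floor approaches −40 dBFS; the threshold is configurable but not
  adaptive by default.
* Only mock/oracle backends ship with the package. Real acoustic-model
  finetuning and language-model rescoring plug in through `asr_backend()`
  but are intentionally out of scope, as are corpus-specific resources and
  any claims about wall-clock transcription speed.
* No significance testing or confidence intervals on WER comparisons —
  the metrics module reports point summaries only.
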