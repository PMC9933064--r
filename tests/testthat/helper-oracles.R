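# Independent brute-force oracles used to pin expected values.
# These deliberately share no code with the package's dynamic-programming
# implementations.

# Needleman-Wunsch global score of two token vectors (end-to-end, linear
# gaps) -- the building block of the local-alignment oracle.
nw_score <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * gap
  D[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap,
                             D[i + 1, j] + gap)
    }
  }
  D[n + 1, m + 1]
}

# Best local alignment score by exhaustive enumeration over all pairs of
# contiguous substrings (the definition of the Smith-Waterman optimum).
sw_oracle_score <- function(q, r, match = 2, mismatch = -1, gap = -1) {
  best <- 0
  if (length(q) == 0 || length(r) == 0) return(0)
  for (qs in seq_along(q)) {
    for (qe in qs:length(q)) {
      for (rs in seq_along(r)) {
        for (re in rs:length(r)) {
          best <- max(best, nw_score(q[qs:qe], r[rs:re],
                                     match, mismatch, gap))
        }
      }
    }
  }
  best
}

# Maximum number of matches over all in-order pairings of substrings: the
# brute-force similarity numerator (longest common subsequence of any
# substring pair equals the LCS of the full sequences).
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  D <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- if (a[i] == b[j]) D[i, j] + 1L else
        max(D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# Minimal unit-cost edit distance by plain recursion with memoisation --
# independent of the package's iterative DP and its traceback.
edit_distance_oracle <- function(r, h) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1, j - 1) + (r[i] != h[j]),
             rec(i - 1, j) + 1,
             rec(i, j - 1) + 1)
    memo[[key]] <- v
    v
  }
  rec(length(r), length(h))
}

# Small, fast synthetic interviews for pipeline tests: low sample rate is
# enough because segmentation only inspects frame energy.
quick_interview <- function(seed, n_utterances = 10, sr = 8000, ...) {
  generate_interview(synth_spec(n_utterances = n_utterances,
                                sample_rate = sr, seed = seed, ...))
}

random_tokens <- function(n, alphabet = c("aa", "bb", "cc", "dd")) {
  if (n == 0) return(character(0))
  sample(alphabet, n, replace = TRUE)
}
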