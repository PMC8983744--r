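# Internal string/sequence helpers shared across modules.
# Package-wide coordinate convention: 0-based, half-open [start, end).

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' @noRd
.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
.comp <- function(x) unname(.COMP[x])

# Translate a nucleotide string starting in frame 0; trailing partial codon
# dropped. Returns "" for inputs shorter than one codon.
#' @noRd
.translate_nt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    cod <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    paste(Biostrings::GENETIC_CODE[cod], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
.stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}

# Deterministic sub-seed derivation: every stochastic stage consumes its own
# named seed derived from the global one, so stages can be rerun in isolation.
#' @noRd
.derive_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, annotate = 23L, stats = 37L, clonal = 53L,
            diverge = 71L, rarefaction = 89L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[stage]]
}

# Longest common substring between two short strings; returns length 0 when
# none at or above min_len. On ties the left-most occurrence in `a` wins,
# then the left-most in `b`. Brute force: inputs here are junction-sized.
#' @noRd
.longest_common_substring <- function(a, b, min_len = 1L) {
  na <- nchar(a); nb <- nchar(b)
  best <- list(len = 0L, a_start = NA_integer_, b_start = NA_integer_, tie = FALSE)
  if (min(na, nb) < min_len) return(best)
  for (len in seq(min(na, nb), min_len)) {
    subs_b <- substring(b, seq_len(nb - len + 1L), seq_len(nb - len + 1L) + len - 1L)
    subs_a <- substring(a, seq_len(na - len + 1L), seq_len(na - len + 1L) + len - 1L)
    hit <- match(subs_a, subs_b)
    ok <- which(!is.na(hit))
    if (length(ok)) {
      i <- ok[1L]
      best <- list(len = len, a_start = i - 1L, b_start = hit[i] - 1L,
                   tie = length(ok) > 1L)
      return(best)
    }
  }
  best
}
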