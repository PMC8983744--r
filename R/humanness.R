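# T20-style humanness scoring: mean percent identity of the top 20 matched
# sequences from a user-supplied human antibody reference set.

#' T20 humanness score
#'
#' Scores antibody variable-region amino-acid sequences against a human
#' reference set: each query is globally aligned (BLOSUM62, affine gaps) to
#' every reference, percent identity is taken as matches over the alignment
#' length, and the score is the mean of the 20 highest identities. With
#' fewer than 20 references all are used and the result is flagged. A
#' variable-region (FR+CDR) score above 79, and a framework-only score
#' above 86, predict low immunogenicity; the threshold applied follows
#' `mode`. Scores are comparable only against the same reference set.
#'
#' @param queries Named character vector of amino-acid sequences, an
#'   `AAStringSet`, or a path to a FASTA file.
#' @param references Human reference set, same accepted forms; for
#'   `mode = "fr_only"` supply framework-only sequences on both sides
#'   (see [extract_framework()]).
#' @param mode `"full"` (FR+CDR, threshold 79) or `"fr_only"`
#'   (threshold 86).
#' @return data.frame with `query_id`, `t20`, `n_matches_used`,
#'   `fewer_than_20`, `threshold`, `pass`.
#' @export
t20_score <- function(queries, references, mode = c("full", "fr_only")) {
  mode <- match.arg(mode)
  queries <- .as_aa_set(queries, "query")
  references <- .as_aa_set(references, "reference")
  if (!length(references)) stop("reference set is empty", call. = FALSE)
  threshold <- if (mode == "full") 79 else 86
  rows <- lapply(seq_along(queries), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = references, subject = queries[[i]],
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 4)
    ident <- Biostrings::pid(aln, type = "PID1")
    top <- sort(ident, decreasing = TRUE)
    n_used <- min(20L, length(top))
    t20 <- mean(top[seq_len(n_used)])
    data.frame(query_id = names(queries)[i], t20 = t20,
               n_matches_used = n_used, fewer_than_20 = n_used < 20L,
               threshold = threshold, pass = t20 > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @noRd
.as_aa_set <- function(x, what) {
  if (inherits(x, "AAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x))
    return(Biostrings::readAAStringSet(x))
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- sprintf("%s_%03d", what, seq_along(x))
    return(Biostrings::AAStringSet(x))
  }
  stop(what, " must be sequences or a FASTA path", call. = FALSE)
}

#' Extract the framework portion of a variable-region sequence
#'
#' Removes the CDR intervals (0-based, half-open, on the amino-acid
#' sequence) and concatenates the remaining framework regions, for
#' framework-only humanness scoring.
#'
#' @param seq_aa Amino-acid sequence.
#' @param cdr_intervals List of `c(start, end)` pairs, 0-based half-open.
#' @return Framework-only sequence string.
#' @export
extract_framework <- function(seq_aa, cdr_intervals) {
  keep <- rep(TRUE, nchar(seq_aa))
  for (iv in cdr_intervals) {
    s <- max(0L, iv[1]); e <- min(nchar(seq_aa), iv[2])
    if (e > s) keep[(s + 1L):e] <- FALSE
  }
  paste(strsplit(seq_aa, "")[[1]][keep], collapse = "")
}
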