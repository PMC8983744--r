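# Germinal-centre divergence analysis: per-read %diversity against the
# germline V, per-lineage Welch tests between two samples, four-group
# classification at a P cutoff, and the overall divergence odds score.

#' Per-read percent diversity from the germline V
#'
#' 100 x (mismatches / aligned V span length) over the aligned V segment
#' only (the junction is excluded). Zero for a germline-identical read.
#'
#' @param tab Annotated rearrangement data.frame.
#' @return Numeric vector, one value per read.
#' @export
percent_diversity <- function(tab) {
  .check_rearr(tab, c("v_mutation_count", "v_germline_start",
                      "v_germline_end"))
  span <- tab$v_germline_end - tab$v_germline_start
  100 * tab$v_mutation_count / pmax(1L, span)
}

#' Shared clone lineages with sufficient depth
#'
#' Lineage keys present in both samples with at least `min_copies` reads in
#' each; below that depth the resolution of %diversity estimation is
#' insufficient for differentiation analysis.
#'
#' @param lineages_s1,lineages_s2 Outputs of [group_lineages()] under the
#'   same key scheme.
#' @param min_copies Minimum reads per sample per lineage (default 100).
#' @return Character vector of lineage keys (possibly empty, with a
#'   warning).
#' @export
filter_lineages <- function(lineages_s1, lineages_s2, min_copies = 100L) {
  k1 <- lineages_s1$lineage_key[lineages_s1$copy_count >= min_copies]
  k2 <- lineages_s2$lineage_key[lineages_s2$copy_count >= min_copies]
  keys <- intersect(k1, k2)
  if (!length(keys))
    warning("no shared lineages with >= ", min_copies,
            " reads in both samples")
  sort(keys)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs are handled explicitly: two
#' zero-variance samples with equal means give `t = 0, p = 1`; with unequal
#' means they give `t = +/-Inf, p = 0`.
#'
#' @param x,y Numeric samples, each of size >= 2 with finite values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    return(list(t = sign(d) * Inf, df = length(x) + length(y) - 2L, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Classify lineages and compute the divergence odds score
#'
#' Given per-lineage Welch statistics comparing the V-segment %diversity of
#' sample 1 against sample 2, each lineage is assigned to one of four
#' groups at the P cutoff: group 1, significantly more diverged in sample
#' 1; group 2, more diverged in sample 1 but not significant; group 3,
#' significantly less diverged in sample 1; group 4, less diverged but not
#' significant. Exact mean ties count as "not more diverged" (groups 3/4).
#' The odds score is `(n1 / n2) / (n3 / n4)`; zero cells trigger a
#' Haldane-Anscombe +0.5 correction on all four counts, flagged in the
#' result. A higher score indicates a repertoire-wide trend of stronger
#' SHM accumulation in sample 1.
#'
#' @param stats_df data.frame with columns `mean1`, `mean2`, `p` (one row
#'   per tested lineage); extra columns are carried through.
#' @param p_cutoff Significance cutoff on the raw p-value (default 0.01).
#' @param adjust Optional multiple-testing adjustment method passed to
#'   [stats::p.adjust()] (default `"none"`, matching classification on raw
#'   p-values).
#' @return Object of class `divergence_result`: list with `lineages`
#'   (input plus `group`), `group_counts`, `odds_score`,
#'   `continuity_corrected`, `p_cutoff`.
#' @export
classify_and_odds <- function(stats_df, p_cutoff = 0.01, adjust = "none") {
  stopifnot(all(c("mean1", "mean2", "p") %in% names(stats_df)))
  p <- stats::p.adjust(stats_df$p, method = adjust)
  more <- stats_df$mean1 > stats_df$mean2
  sig <- p < p_cutoff
  group <- ifelse(more, ifelse(sig, 1L, 2L), ifelse(sig, 3L, 4L))
  counts <- vapply(1:4, function(g) sum(group == g), integer(1))
  corrected <- any(counts == 0L)
  cc <- if (corrected) counts + 0.5 else counts
  odds <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  out <- stats_df
  out$p_adjusted <- p
  out$group <- group
  structure(list(lineages = out,
                 group_counts = stats::setNames(counts, paste0("group", 1:4)),
                 odds_score = odds,
                 continuity_corrected = corrected,
                 p_cutoff = p_cutoff),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("divergence_result: %d lineages tested (P cutoff %g)\n",
              nrow(x$lineages), x$p_cutoff))
  print(x$group_counts)
  cat(sprintf("odds score = %.4f%s\n", x$odds_score,
              if (x$continuity_corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Between-sample lineage divergence analysis
#'
#' End-to-end driver: groups both samples into clone lineages, keeps shared
#' lineages with at least `min_copies` reads each, runs a Welch test on the
#' per-read V-segment %diversity of each lineage, classifies the lineages
#' into the four divergence groups and returns the odds score.
#'
#' @param tab1,tab2 Annotated rearrangement data.frames for sample 1 and
#'   sample 2.
#' @param min_copies Minimum reads per sample per lineage (default 100).
#' @param p_cutoff Welch p-value cutoff (default 0.01).
#' @param level Lineage grouping level (`"gene"` or `"allele"`).
#' @param adjust Multiple-testing adjustment (default `"none"`).
#' @return A `divergence_result` (see [classify_and_odds()]); its
#'   `lineages` element carries `lineage_key`, sample sizes, means, Welch
#'   `t`, `df`, `p` and `group`.
#' @export
divergence_odds <- function(tab1, tab2, min_copies = 100L, p_cutoff = 0.01,
                            level = "gene", adjust = "none") {
  l1 <- group_lineages(tab1, level = level)
  l2 <- group_lineages(tab2, level = level)
  keys <- filter_lineages(l1, l2, min_copies)
  if (!length(keys))
    stop("no testable lineages shared by both samples", call. = FALSE)
  pd1 <- percent_diversity(tab1)
  pd2 <- percent_diversity(tab2)
  k1 <- .lineage_key(tab1, level)
  k2 <- .lineage_key(tab2, level)
  rows <- lapply(keys, function(k) {
    x <- pd1[k1 == k]; y <- pd2[k2 == k]
    w <- welch_test(x, y)
    data.frame(lineage_key = k, n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  classify_and_odds(do.call(rbind, rows), p_cutoff = p_cutoff,
                    adjust = adjust)
}
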