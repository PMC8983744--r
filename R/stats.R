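# Repertoire-level descriptive statistics: segment usage, V(D)J combination
# links (with Circos-format export), CDR3 length and amino-acid composition,
# P/N addition distributions, productive fraction, Shannon-Weaver diversity
# and rarefaction.

#' @noRd
.check_rearr <- function(tab, cols = c("v_call")) {
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    stop("rearrangement table is empty", call. = FALSE)
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("rearrangement table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @noRd
.weights <- function(tab, weight_by_duplicates) {
  if (weight_by_duplicates && "duplicate_count" %in% names(tab))
    as.numeric(tab$duplicate_count) else rep(1, nrow(tab))
}

#' Segment usage frequencies
#'
#' Percentage frequency of use of V, D or J gene segments over the annotated
#' reads of one sample. For D, reads with an unassigned D call are excluded
#' from the denominator and reported in the `n_unassigned` attribute.
#'
#' @param tab Annotated rearrangement data.frame.
#' @param segment_type `"V"`, `"D"` or `"J"`.
#' @param weight_by_duplicates Weight reads by `duplicate_count`
#'   (default `FALSE`: unique annotated reads).
#' @param productive_only Restrict to productive reads (default `FALSE`).
#' @return data.frame with `segment_id`, `read_count`, `percent_frequency`
#'   (sums to 100).
#' @export
usage_frequencies <- function(tab, segment_type = c("V", "D", "J"),
                              weight_by_duplicates = FALSE,
                              productive_only = FALSE) {
  segment_type <- match.arg(segment_type)
  col <- paste0(tolower(segment_type), "_call")
  .check_rearr(tab, col)
  if (productive_only) tab <- tab[isTRUE_v(tab$productive), , drop = FALSE]
  w <- .weights(tab, weight_by_duplicates)
  calls <- tab[[col]]
  n_unassigned <- sum(w[is.na(calls)])
  keep <- !is.na(calls)
  if (!any(keep)) stop("no assigned ", segment_type, " calls", call. = FALSE)
  counts <- tapply(w[keep], calls[keep], sum)
  out <- data.frame(segment_id = names(counts),
                    read_count = as.numeric(counts),
                    percent_frequency = 100 * as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$segment_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' @noRd
isTRUE_v <- function(x) !is.na(x) & x

#' V(D)J combination links
#'
#' Counts of observed V-(D-)J recombination partner combinations,
#' normalized to relative frequencies, at gene or allele grouping level
#' (gene level strips the `*NN` allele suffix).
#'
#' @param tab Annotated rearrangement data.frame.
#' @param grouping_level `"gene"` or `"allele"`.
#' @param weight_by_duplicates Weight by `duplicate_count`.
#' @return data.frame with `v_group`, `d_group` (NA for IGK), `j_group`,
#'   `count`, `relative_frequency` (sums to 1).
#' @export
vdj_links <- function(tab, grouping_level = c("gene", "allele"),
                      weight_by_duplicates = FALSE) {
  grouping_level <- match.arg(grouping_level)
  .check_rearr(tab, c("v_call", "j_call"))
  tab <- tab[!is.na(tab$v_call) & !is.na(tab$j_call), , drop = FALSE]
  if (!nrow(tab)) stop("no reads with both V and J calls", call. = FALSE)
  grp <- function(x) if (grouping_level == "gene") sub("\\*.*$", "", x) else x
  w <- .weights(tab, weight_by_duplicates)
  d <- if ("d_call" %in% names(tab)) grp(tab$d_call) else rep(NA_character_, nrow(tab))
  key <- paste(grp(tab$v_call), ifelse(is.na(d), "", d), grp(tab$j_call),
               sep = "\t")
  counts <- tapply(w, key, sum)
  parts <- do.call(rbind, strsplit(names(counts), "\t", fixed = TRUE))
  out <- data.frame(v_group = parts[, 1],
                    d_group = ifelse(parts[, 2] == "", NA_character_, parts[, 2]),
                    j_group = parts[, 3],
                    count = as.numeric(counts),
                    relative_frequency = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$v_group, out$j_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export combination links in Circos text format
#'
#' Writes a karyotype file (one band per segment group, band size
#' proportional to the group's observed frequency) and a links file, the
#' plain-text inputs of the Circos chord-diagram tool. Rendering itself is
#' left to Circos.
#'
#' @param links Output of [vdj_links()].
#' @param path_prefix Output prefix; writes `<prefix>_karyotype.txt` and
#'   `<prefix>_links.txt`.
#' @return Invisibly, the two paths.
#' @export
circos_export <- function(links, path_prefix) {
  scale <- 1000
  grp_size <- function(col) {
    s <- tapply(links$relative_frequency, links[[col]], sum)
    s[!is.na(names(s))]
  }
  kar <- character(0)
  for (col in c("v_group", "d_group", "j_group")) {
    if (all(is.na(links[[col]]))) next
    sz <- grp_size(col)
    kar <- c(kar, sprintf("chr - %s %s 0 %d grey",
                          names(sz), names(sz),
                          pmax(1L, as.integer(round(scale * sz)))))
  }
  kpath <- paste0(path_prefix, "_karyotype.txt")
  lpath <- paste0(path_prefix, "_links.txt")
  writeLines(kar, kpath)
  lk <- links
  lk$d_group[is.na(lk$d_group)] <- "-"
  writeLines(sprintf("%s %s %s %.10g %.10g", lk$v_group, lk$d_group,
                     lk$j_group, lk$count, lk$relative_frequency), lpath)
  invisible(c(kpath, lpath))
}

#' Read a Circos links file written by [circos_export()]
#'
#' @param path Path to a `*_links.txt` file.
#' @return data.frame in the [vdj_links()] layout.
#' @export
read_circos_links <- function(path) {
  raw <- utils::read.table(path, stringsAsFactors = FALSE,
                           col.names = c("v_group", "d_group", "j_group",
                                         "count", "relative_frequency"))
  raw$d_group[raw$d_group == "-"] <- NA_character_
  raw
}

#' CDR3 amino-acid length distribution
#'
#' Histogram of CDR3 amino-acid lengths and their mean over productive
#' rearrangements (the set over which CDR3 statistics are defined).
#'
#' @param tab Annotated rearrangement data.frame.
#' @param weight_by_duplicates Weight by `duplicate_count`.
#' @return List with `histogram` (data.frame `length`, `count`) and
#'   `mean_length` (2 decimals).
#' @export
cdr3_length_distribution <- function(tab, weight_by_duplicates = FALSE) {
  .check_rearr(tab, c("cdr3_aa", "productive"))
  tab <- tab[isTRUE_v(tab$productive) & !is.na(tab$cdr3_aa) &
             nzchar(tab$cdr3_aa), , drop = FALSE]
  if (!nrow(tab)) stop("no productive reads with a CDR3", call. = FALSE)
  w <- .weights(tab, weight_by_duplicates)
  len <- nchar(tab$cdr3_aa)
  counts <- tapply(w, len, sum)
  hist <- data.frame(length = as.integer(names(counts)),
                     count = as.numeric(counts))
  hist <- hist[order(hist$length), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist,
       mean_length = round(sum(w * len) / sum(w), 2))
}

#' Amino-acid composition of CDR3 sequences
#'
#' Per-residue frequencies over the concatenated CDR3 amino-acid sequences
#' of productive reads; frequencies sum to 1.
#'
#' @inheritParams cdr3_length_distribution
#' @return data.frame with `residue` and `frequency` for the 20 standard
#'   amino acids.
#' @export
aa_composition <- function(tab, weight_by_duplicates = FALSE) {
  .check_rearr(tab, c("cdr3_aa", "productive"))
  tab <- tab[isTRUE_v(tab$productive) & !is.na(tab$cdr3_aa) &
             nzchar(tab$cdr3_aa), , drop = FALSE]
  if (!nrow(tab)) stop("no productive reads with a CDR3", call. = FALSE)
  w <- .weights(tab, weight_by_duplicates)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  counts <- stats::setNames(numeric(length(aas)), aas)
  for (i in seq_len(nrow(tab))) {
    ch <- strsplit(tab$cdr3_aa[i], "")[[1]]
    t <- table(factor(ch, levels = aas))
    counts <- counts + w[i] * as.numeric(t)
  }
  data.frame(residue = aas, frequency = counts / sum(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' P/N addition length distributions
#'
#' Histograms and means of the junctional N-insert lengths (`n1`; and `n2`
#' for IGH) and of the P-nucleotide lengths at each junction end.
#'
#' @param tab Annotated rearrangement data.frame.
#' @return Named list of data.frames (`length`, `count`) for `n1`, `n2`,
#'   and each P end present, plus a `means` named vector.
#' @export
np_addition_distribution <- function(tab) {
  .check_rearr(tab, "n1_length")
  cols <- intersect(c("n1_length", "n2_length", "p_v_length", "p_d5_length",
                      "p_d3_length", "p_j_length"), names(tab))
  out <- list()
  means <- c()
  for (col in cols) {
    x <- tab[[col]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    t <- table(x)
    nm <- sub("_length$", "", col)
    out[[nm]] <- data.frame(length = as.integer(names(t)),
                            count = as.numeric(t))
    means[nm] <- mean(x)
  }
  out$means <- means
  out
}

#' Fraction of productive rearrangements
#'
#' @param tab Annotated rearrangement data.frame.
#' @param weight_by_duplicates Weight by `duplicate_count`.
#' @return Percent of annotated reads that are productive.
#' @export
productive_fraction <- function(tab, weight_by_duplicates = FALSE) {
  .check_rearr(tab, "productive")
  w <- .weights(tab, weight_by_duplicates)
  100 * sum(w[isTRUE_v(tab$productive)]) / sum(w)
}

#' Shannon-Weaver diversity index
#'
#' Computes the Shannon-Weaver index
#' \deqn{H' = -\sum_{i=1}^{S} \frac{n_i}{N} \ln \frac{n_i}{N}}
#' over species abundances `n_i` (natural logarithm), where `N` is the total
#' count and `S` the number of species. A greater H' reflects greater sample
#' diversity; `0 <= H' <= ln(S)` with equality at a single species and at
#' uniform abundances respectively.
#'
#' @param counts Vector of positive species counts (drop zeros beforehand).
#' @return Object of class `diversity_result`: list with `H_prime`, `N`,
#'   `S`, `counts`.
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0L) stop("counts is empty", call. = FALSE)
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  N <- sum(counts)
  p <- counts / N
  H <- -sum(p * log(p))
  structure(list(H_prime = H, N = N, S = length(counts), counts = counts),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Shannon-Weaver H' = %.4f (S = %d species, N = %g reads, max ln S = %.4f)\n",
              x$H_prime, x$S, x$N, log(x$S)))
  invisible(x)
}

#' @noRd
.clonotype_key <- function(tab) {
  .check_rearr(tab, c("cdr1_aa", "cdr2_aa", "cdr3_aa"))
  paste(tab$cdr1_aa, tab$cdr2_aa, tab$cdr3_aa, sep = "|")
}

#' Rarefaction curve of clonotype richness
#'
#' Mean number of distinct clonotypes (CDR1-2-3 joined amino-acid key)
#' observed in uniform subsamples without replacement of the reads, at each
#' requested depth. Monotone non-decreasing in depth and bounded by the
#' total clonotype count.
#'
#' @param tab Annotated rearrangement data.frame.
#' @param depths Integer vector of subsample sizes (each `<=` nrow(tab)).
#' @param replicates Subsamples per depth (default 20).
#' @return data.frame with `depth` and `mean_distinct`.
#' @export
rarefaction_curve <- function(tab, depths, replicates = 20L) {
  keys <- .clonotype_key(tab)
  n <- length(keys)
  if (any(depths > n)) stop("depths must not exceed the read count",
                            call. = FALSE)
  mean_distinct <- vapply(depths, function(d) {
    mean(vapply(seq_len(replicates), function(r)
      length(unique(keys[sample.int(n, d)])), numeric(1)))
  }, numeric(1))
  data.frame(depth = as.integer(depths), mean_distinct = mean_distinct)
}
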