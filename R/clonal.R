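# Clonotype and clone-lineage grouping, lineage expansion fold change,
# per-position SHM profiling on a length-normalized 1..100 index, mutation
# burden, and neighbor-joining clonal dendrograms with copy-number overlays.

#' Group reads into clonotypes
#'
#' A clonotype is a unique antibody sequence identity defined by the joined
#' CDR1-CDR2-CDR3 amino-acid sequence; reads identical over the three CDRs
#' form one clonotype regardless of framework differences.
#'
#' @param tab Annotated rearrangement data.frame (needs `cdr1_aa`,
#'   `cdr2_aa`, `cdr3_aa`).
#' @return data.frame with `clonotype_key`, `copy_count`
#'   (sum of `duplicate_count`), `n_reads`, `read_ids` (comma-joined),
#'   sorted by descending copy count then key.
#' @export
group_clonotypes <- function(tab) {
  key <- .clonotype_key(tab)
  w <- .weights(tab, TRUE)
  sp <- split(seq_len(nrow(tab)), key)
  out <- data.frame(
    clonotype_key = names(sp),
    copy_count = vapply(sp, function(i) sum(w[i]), numeric(1)),
    n_reads = lengths(sp),
    read_ids = vapply(sp, function(i)
      paste(tab$sequence_id[i], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$clonotype_key, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
.lineage_key <- function(tab, level, strict_cdr3_length = FALSE) {
  grp <- function(x) if (level == "gene") sub("\\*.*$", "", x) else x
  d <- if ("d_call" %in% names(tab)) {
    ifelse(is.na(tab$d_call), "unassigned", grp(tab$d_call))
  } else "none"
  key <- paste(grp(tab$v_call), d, grp(tab$j_call), sep = "_")
  if (strict_cdr3_length)
    key <- paste(key, nchar(tab$cdr3_aa), sep = "_")
  key
}

#' Group reads into clone lineages
#'
#' A clone lineage approximates the set of B cells arising from one V(D)J
#' rearrangement event, operationalized as the combination of V-D-J segment
#' typing. Lineages are named by descending copy-count rank (`CLH001`, ...
#' for IGH; `CLL001`, ... for IGK), ties broken by key order.
#'
#' @param tab Annotated rearrangement data.frame.
#' @param level `"gene"` (default: alleles of one gene merge) or `"allele"`.
#' @param strict_cdr3_length Also require equal CDR3 amino-acid length
#'   within a lineage (stricter proxy for a single rearrangement event).
#' @return data.frame with `lineage_key`, `name`, `copy_count`, `n_reads`,
#'   `mean_length` (mean variable-region read length), `read_ids`.
#' @export
group_lineages <- function(tab, level = c("gene", "allele"),
                           strict_cdr3_length = FALSE) {
  level <- match.arg(level)
  .check_rearr(tab, c("v_call", "j_call"))
  key <- .lineage_key(tab, level, strict_cdr3_length)
  w <- .weights(tab, TRUE)
  sp <- split(seq_len(nrow(tab)), key)
  lens <- if ("sequence" %in% names(tab)) nchar(tab$sequence) else
    rep(NA_real_, nrow(tab))
  out <- data.frame(
    lineage_key = names(sp),
    copy_count = vapply(sp, function(i) sum(w[i]), numeric(1)),
    n_reads = lengths(sp),
    mean_length = vapply(sp, function(i) mean(lens[i]), numeric(1)),
    read_ids = vapply(sp, function(i)
      paste(tab$sequence_id[i], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$lineage_key, method = "radix"), ,
             drop = FALSE]
  prefix <- if ("locus" %in% names(tab) && any(tab$locus == "IGK"))
    "CLL" else "CLH"
  out$name <- sprintf("%s%03d", prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("lineage_key", "name", "copy_count", "n_reads", "mean_length",
          "read_ids")]
}

#' Top-n clone lineages
#'
#' The n most frequently used lineages by copy count (ties by key order,
#' deterministic). Returns the whole table when n exceeds it.
#'
#' @param lineages Output of [group_lineages()].
#' @param n Number of lineages to keep.
#' @return Subset of `lineages`, rank order preserved.
#' @export
top_lineages <- function(lineages, n) {
  utils::head(lineages, n)
}

#' Per-lineage expansion fold change between two samples
#'
#' Fold change of lineage copy numbers between a pre and a post sample
#' (e.g. before/after immunization), with copies normalized per
#' `per_reads` annotated reads to remove depth differences. Lineages absent
#' from the pre sample receive a pseudocount of one normalized copy and are
#' flagged (`pseudocount_used`), never silently.
#'
#' @param lineages_pre,lineages_post Outputs of [group_lineages()] built
#'   with the same key scheme.
#' @param per_reads Normalization depth (default 1e4).
#' @return data.frame keyed on the union of post-sample lineages with
#'   normalized copies, `fold_change`, and `pseudocount_used`.
#' @export
lineage_fold_change <- function(lineages_pre, lineages_post,
                                per_reads = 1e4) {
  tot_pre <- sum(lineages_pre$copy_count)
  tot_post <- sum(lineages_post$copy_count)
  i <- match(lineages_post$lineage_key, lineages_pre$lineage_key)
  pre_norm <- ifelse(is.na(i), NA_real_,
                     lineages_pre$copy_count[i] / tot_pre * per_reads)
  pseudo <- is.na(pre_norm)
  pre_norm[pseudo] <- 1
  post_norm <- lineages_post$copy_count / tot_post * per_reads
  data.frame(lineage_key = lineages_post$lineage_key,
             name = lineages_post$name,
             pre_normalized = pre_norm, post_normalized = post_norm,
             fold_change = post_norm / pre_norm,
             pseudocount_used = pseudo,
             stringsAsFactors = FALSE)
}

#' @noRd
.parse_v_mutations <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(sub("^([0-9]+).*$", "\\1",
                 strsplit(s, ",", fixed = TRUE)[[1]]))
}

#' Raw per-position SHM rates of a clone lineage
#'
#' For each germline V position, the percentage of lineage member reads
#' mutated at that position, among the reads whose V alignment covers it
#' (e.g. 3 mutated reads out of 10 covering gives 30%).
#'
#' @param tab Annotated rearrangement data.frame restricted to one lineage's
#'   member reads (all sharing a resolvable germline V).
#' @param db A `germline_db`.
#' @return data.frame with `position` (0-based germline V coordinate),
#'   `n_covered`, `n_mutated`, `rate` (percent); plus attributes
#'   `mean_length` (mean variable-region read length) and `v_call`.
#' @export
shm_position_profile <- function(tab, db) {
  .check_rearr(tab, c("v_call", "v_germline_start", "v_germline_end",
                      "v_mutations"))
  if (nrow(tab) == 0L) stop("lineage has no member reads", call. = FALSE)
  v_genes <- unique(sub("\\*.*$", "", tab$v_call))
  if (length(v_genes) > 1L)
    stop("lineage members carry different germline V genes: ",
         paste(v_genes, collapse = ", "), call. = FALSE)
  vlen <- max(nchar(db$sequences[unique(tab$v_call)]))
  n_cov <- integer(vlen)
  n_mut <- integer(vlen)
  for (i in seq_len(nrow(tab))) {
    s <- tab$v_germline_start[i]; e <- tab$v_germline_end[i]
    if (e > s) n_cov[(s + 1L):e] <- n_cov[(s + 1L):e] + 1L
    pos <- .parse_v_mutations(tab$v_mutations[i])
    n_mut[pos + 1L] <- n_mut[pos + 1L] + 1L
  }
  out <- data.frame(position = seq_len(vlen) - 1L,
                    n_covered = n_cov, n_mutated = n_mut,
                    rate = ifelse(n_cov > 0L, 100 * n_mut / n_cov, 0))
  attr(out, "mean_length") <- if ("sequence" %in% names(tab))
    mean(nchar(tab$sequence)) else vlen
  attr(out, "v_call") <- tab$v_call[1]
  out
}

#' Normalize a raw SHM profile to a 1..100 length index
#'
#' Variable-region lengths differ between reads, so raw germline positions
#' are mapped to a common index: position p (0-based) goes to
#' `round(100 * (p + 1) / mean_length)`, clipped to `[1, 100]`; rates are
#' averaged within an index bin and bins receiving no position get rate 0.
#' On this index, clone lineages of different lengths are comparable and an
#' index unit is close to one amino-acid position of the variable region.
#' Each index carries a region label (FR1/CDR1/FR2/CDR2/FR3/CDR3, plus FR4
#' well beyond the germline V end) derived from the germline V annotation.
#'
#' @param raw Output of [shm_position_profile()].
#' @param db A `germline_db`.
#' @param mean_length Mean variable-region length of the lineage; defaults
#'   to the `mean_length` attribute of `raw`.
#' @return Object of class `mutation_profile`: data.frame with `index`
#'   (1..100), `rate` (percent), `region`.
#' @export
normalize_profile <- function(raw, db, mean_length = attr(raw, "mean_length")) {
  stopifnot(!is.null(mean_length), mean_length > 0)
  v_call <- attr(raw, "v_call")
  vmeta <- .segment_meta(db, v_call)
  vlen <- nchar(db$sequences[[v_call]])
  idx <- pmin(100L, pmax(1L, as.integer(round(100 * (raw$position + 1) /
                                              mean_length))))
  rate <- vapply(1:100, function(i) {
    r <- raw$rate[idx == i]
    if (length(r)) mean(r) else 0
  }, numeric(1))
  # region of the representative germline position of each index
  gpos <- pmax(0, round(seq_len(100) * mean_length / 100) - 1)
  region <- vapply(gpos, function(g) {
    if (!is.na(vmeta$cdr1_start) && g >= vmeta$cdr1_start &&
        g < vmeta$cdr1_end) return("CDR1")
    if (!is.na(vmeta$cdr2_start) && g >= vmeta$cdr2_start &&
        g < vmeta$cdr2_end) return("CDR2")
    if (g < ifelse(is.na(vmeta$cdr1_start), vmeta$anchor_offset,
                   vmeta$cdr1_start)) return("FR1")
    if (!is.na(vmeta$cdr2_start) && g < vmeta$cdr2_start) return("FR2")
    if (g < vmeta$anchor_offset) return("FR3")
    if (g < vlen + 20) return("CDR3")
    "FR4"
  }, character(1))
  structure(data.frame(index = 1:100, rate = rate, region = region),
            class = c("mutation_profile", "data.frame"))
}

#' @export
print.mutation_profile <- function(x, ...) {
  peak <- x$index[which.max(x$rate)]
  cat(sprintf("mutation_profile: 100 indices, max rate %.2f%% at index %d (%s)\n",
              max(x$rate), peak, x$region[which.max(x$rate)]))
  invisible(x)
}

#' Aggregate normalized SHM profiles across lineages
#'
#' Combines per-lineage `mutation_profile`s (e.g. of the top 70 heavy or
#' top 20 kappa lineages) into one landscape by the per-index mean rate —
#' unweighted by default so a single expanded lineage does not dominate,
#' or weighted (e.g. by lineage copy counts).
#'
#' @param profiles List of [normalize_profile()] outputs.
#' @param weights Optional non-negative weights, one per profile.
#' @return A `mutation_profile` (regions taken from the first profile).
#' @export
aggregate_profiles <- function(profiles, weights = NULL) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(profiles))
  stopifnot(length(weights) == length(profiles), all(weights >= 0),
            sum(weights) > 0)
  rates <- vapply(profiles, function(p) p$rate, numeric(100))
  rate <- as.numeric(rates %*% (weights / sum(weights)))
  structure(data.frame(index = 1:100, rate = rate,
                       region = profiles[[1]]$region),
            class = c("mutation_profile", "data.frame"))
}

#' Mutation burden of a clone lineage
#'
#' Percentage of member reads carrying at least `min_mutations` point
#' mutations in the variable region.
#'
#' @param tab Annotated rearrangement data.frame of the lineage members.
#' @param min_mutations Threshold (default 2).
#' @return Percent of reads at or above the threshold.
#' @export
shm_burden <- function(tab, min_mutations = 2L) {
  .check_rearr(tab, "v_mutation_count")
  100 * mean(tab$v_mutation_count >= min_mutations)
}

#' Neighbor-joining clonal dendrogram
#'
#' Builds an unrooted neighbor-joining tree over amino-acid sequences
#' (typically the CDR3 of a lineage's clonotypes) from normalized edit
#' distances (Levenshtein distance divided by the longer length). Leaf
#' copy-number overlays are capped at `max_overlay` reads, with the cap
#' recorded per leaf.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (>= 1; names become tip labels).
#' @param copy_counts Integer copy numbers per sequence (default all 1).
#' @param max_overlay Overlay cap (default 50).
#' @param distances Optional precomputed distance matrix (overrides the
#'   normalized edit distances).
#' @return Object of class `clonal_tree`: list with `tree` (an [ape]
#'   `phylo`), `overlay` (data.frame `label`, `copy_count`, `overlay`,
#'   `capped`), and `distances`.
#' @export
nj_tree <- function(sequences, copy_counts = NULL, max_overlay = 50L,
                    distances = NULL) {
  n <- length(sequences)
  if (n < 1L) stop("need at least one sequence", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_len(n))
  if (is.null(copy_counts)) copy_counts <- rep(1L, n)
  if (is.null(distances)) {
    d <- utils::adist(sequences) /
      outer(nchar(sequences), nchar(sequences), pmax)
  } else {
    d <- as.matrix(distances)
    stopifnot(nrow(d) == n, ncol(d) == n)
  }
  dimnames(d) <- list(names(sequences), names(sequences))
  if (n == 1L) {
    tree <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           edge.length = 0, tip.label = names(sequences),
                           Nnode = 1L), class = "phylo")
  } else if (n == 2L) {
    tree <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L,
                                         byrow = TRUE),
                           edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                           tip.label = names(sequences), Nnode = 1L),
                      class = "phylo")
  } else {
    tree <- ape::nj(stats::as.dist(d))
  }
  overlay <- data.frame(label = names(sequences),
                        copy_count = copy_counts,
                        overlay = pmin(copy_counts, max_overlay),
                        capped = copy_counts > max_overlay,
                        stringsAsFactors = FALSE)
  structure(list(tree = tree, overlay = overlay, distances = d),
            class = "clonal_tree")
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat("clonal_tree:", length(x$tree$tip.label), "tips;",
      sum(x$overlay$capped), "overlay value(s) capped\n")
  invisible(x)
}

#' Write a clonal tree to Newick
#'
#' @param x A `clonal_tree`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_clonal_tree <- function(x, path) {
  stopifnot(inherits(x, "clonal_tree"))
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

#' Subset the member reads of a lineage from a rearrangement table
#'
#' @param tab Annotated rearrangement data.frame.
#' @param lineages Output of [group_lineages()].
#' @param name_or_key A lineage `name` (e.g. `"CLH001"`) or `lineage_key`.
#' @return The member rows of `tab`.
#' @export
lineage_reads <- function(tab, lineages, name_or_key) {
  i <- match(name_or_key, lineages$name)
  if (is.na(i)) i <- match(name_or_key, lineages$lineage_key)
  if (is.na(i)) stop("unknown lineage: ", name_or_key, call. = FALSE)
  ids <- strsplit(lineages$read_ids[i], ",", fixed = TRUE)[[1]]
  tab[tab$sequence_id %in% ids, , drop = FALSE]
}
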