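#' Simulation configuration for a synthetic V(D)J repertoire
#'
#' Bundles and validates the generative parameters of the repertoire
#' simulator. Segment usage is given as named probability vectors over
#' segment ids (default: uniform over the functional segments of the locus).
#' Exonucleolytic trimming at each junction-facing segment end is geometric
#' with mean `trim_mean`; P (palindromic) nucleotides occur with probability
#' `p_prob` at each *untrimmed* end with truncated-geometric length capped at
#' `p_maxlen`; non-templated N inserts have geometric length with mean
#' `n_mean` and uniform base composition. Somatic hypermutation is an
#' independent per-base substitution process at rate `shm_rate`, multiplied
#' by `hotspot_multiplier` inside CDR positions (CDR1/CDR2 from the germline
#' metadata plus the CDR3 junction span). When `n_lineages` is set, reads
#' are clonal copies of founder rearrangements, each copy mutated
#' independently from the founder (star topology).
#'
#' @param n_reads Number of reads to emit.
#' @param locus `"IGH"` (V-D-J) or `"IGK"` (V-J).
#' @param v_usage,d_usage,j_usage Named non-negative vectors summing to 1
#'   over segment ids, or `NULL` for uniform over functional segments.
#' @param trim_mean Mean of the geometric trim-length distribution (nt).
#' @param p_prob Probability of a P extension at an untrimmed end.
#' @param p_maxlen Maximum P length (nt).
#' @param n_mean Mean of the geometric N-insert length distribution (nt).
#' @param shm_rate Per-base substitution probability in `[0, 1]`.
#' @param hotspot_multiplier Rate multiplier (>= 0) inside CDR positions.
#' @param n_lineages Number of founder rearrangements, or `NULL` for fully
#'   independent reads.
#' @param expansion_copies Copies per lineage: a single integer (fixed) or
#'   `NULL` to split `n_reads` uniformly at random across lineages.
#' @param min_d_match Minimum consecutive germline-matching bases for a D
#'   segment to be identifiable (kept consistent with the annotator).
#' @param seed RNG seed consumed by [simulate_repertoire()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1000L, locus = c("IGH", "IGK"),
                       v_usage = NULL, d_usage = NULL, j_usage = NULL,
                       trim_mean = 1.5, p_prob = 0.3, p_maxlen = 4L,
                       n_mean = 4, shm_rate = 0, hotspot_multiplier = 1,
                       n_lineages = NULL, expansion_copies = NULL,
                       min_d_match = 5L, seed = 1L) {
  locus <- match.arg(locus)
  cfg <- list(n_reads = as.integer(n_reads), locus = locus,
              v_usage = v_usage, d_usage = d_usage, j_usage = j_usage,
              trim_mean = trim_mean, p_prob = p_prob,
              p_maxlen = as.integer(p_maxlen), n_mean = n_mean,
              shm_rate = shm_rate, hotspot_multiplier = hotspot_multiplier,
              n_lineages = if (is.null(n_lineages)) NULL else as.integer(n_lineages),
              expansion_copies = if (is.null(expansion_copies)) NULL
                                 else as.integer(expansion_copies),
              min_d_match = as.integer(min_d_match), seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
.validate_sim_config <- function(cfg) {
  if (cfg$n_reads < 1L) stop("n_reads must be positive", call. = FALSE)
  for (u in c("v_usage", "d_usage", "j_usage")) {
    v <- cfg[[u]]
    if (is.null(v)) next
    if (is.null(names(v)) || any(v < 0))
      stop(u, " must be a named non-negative vector", call. = FALSE)
    if (abs(sum(v) - 1) > 1e-9)
      stop(u, " must sum to 1 (got ", sum(v), ")", call. = FALSE)
  }
  if (cfg$shm_rate < 0 || cfg$shm_rate > 1)
    stop("shm_rate must be in [0, 1]", call. = FALSE)
  if (cfg$hotspot_multiplier < 0)
    stop("hotspot_multiplier must be >= 0", call. = FALSE)
  if (cfg$trim_mean < 0 || cfg$n_mean < 0)
    stop("trim_mean and n_mean must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' @noRd
.usage_or_uniform <- function(usage, db, locus, type) {
  if (!is.null(usage)) {
    missing <- setdiff(names(usage), db$segments$id)
    if (length(missing))
      stop("usage names not in germline db: ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(usage)
  }
  ids <- functional_segments(db, locus, type)$id
  if (!length(ids)) stop("no functional ", locus, " ", type,
                         " segments in db", call. = FALSE)
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}

#' @noRd
.rgeom1 <- function(mean) {
  if (mean <= 0) return(0L)
  stats::rgeom(1L, 1 / (1 + mean))
}

#' @noRd
.sample_p_len <- function(p_prob, p_maxlen) {
  if (p_maxlen < 1L || stats::runif(1L) >= p_prob) return(0L)
  min(1L + stats::rgeom(1L, 0.5), p_maxlen)
}

#' @noRd
.rand_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# ---- canonicality checks -----------------------------------------------
# The emitted truth record must be the *canonical* decomposition of the
# read: the one a maximal-germline-match junction caller recovers. Random
# junctional bases that happen to extend a germline segment match (or a P
# palindrome, or blur the D placement) make the sampled decomposition
# unidentifiable, so such junctions are resampled. These checks are coded
# directly from the maximal-match rules, independently of the annotate
# module's decomposition routine.

# Would a +1/-1 local aligner extend the segment match into `follow`?
# `tail` holds the trimmed-off germline bases adjacent to the boundary,
# ordered outward from the kept part. Reject when any prefix score >= 0.
#' @noRd
.extends_alignment <- function(tail, follow) {
  k <- min(nchar(tail), nchar(follow))
  if (k == 0L) return(FALSE)
  t <- strsplit(substr(tail, 1L, k), "")[[1]]
  f <- strsplit(substr(follow, 1L, k), "")[[1]]
  any(cumsum(ifelse(t == f, 1L, -1L)) >= 0L)
}

# Greedy P length read outward from an untrimmed segment end.
# `end_bases`: germline bases at the end, ordered from the boundary outward
# (for a 3' end: last base first; for a 5' end: first base first).
# `region`: junction bases ordered from the boundary outward.
#' @noRd
.greedy_p_len <- function(end_bases, region, p_maxlen) {
  k <- min(nchar(end_bases), nchar(region), p_maxlen)
  g <- 0L
  if (k == 0L) return(0L)
  e <- strsplit(substr(end_bases, 1L, k), "")[[1]]
  r <- strsplit(substr(region, 1L, k), "")[[1]]
  for (i in seq_len(k)) {
    if (r[i] == .comp(e[i])) g <- i else break
  }
  g
}

#' @noRd
.rev_chars <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# Check that the sampled IGH/IGK junction is canonical. Returns TRUE/FALSE.
#' @noRd
.junction_canonical <- function(parts, vseq, dseq, jseq, d_pool,
                                cfg) {
  p <- parts
  after_v <- paste0(p$p_v, p$n1, p$p_d5, p$dpart, p$p_d3, p$n2, p$p_j)
  gap <- after_v                      # between kept V and kept J
  before_j <- gap
  # V 3' boundary
  if (p$v_trim > 0L) {
    tail_v <- substr(vseq, nchar(vseq) - p$v_trim + 1L, nchar(vseq))
    if (.extends_alignment(tail_v, gap)) return(FALSE)
  } else {
    endb <- .rev_chars(vseq)          # last base first
    if (.greedy_p_len(endb, gap, cfg$p_maxlen) != nchar(p$p_v)) return(FALSE)
  }
  # J 5' boundary (scan leftward from the J start)
  rev_gap <- .rev_chars(before_j)
  if (p$j_trim > 0L) {
    tail_j <- .rev_chars(substr(jseq, 1L, p$j_trim))  # J[j_trim-1], J[j_trim-2], ...
    if (.extends_alignment(tail_j, rev_gap)) return(FALSE)
  } else {
    if (.greedy_p_len(jseq, rev_gap, cfg$p_maxlen) != nchar(p$p_j)) return(FALSE)
  }
  if (is.null(dseq)) return(TRUE)     # IGK: done
  # D placement: the trimmed D must be the unique, exact, non-extendable
  # longest germline-D substring of the gap.
  dlen_kept <- nchar(p$dpart)
  if (dlen_kept < cfg$min_d_match) return(FALSE)
  d_pos <- nchar(p$p_v) + nchar(p$n1) + nchar(p$p_d5)   # 0-based in gap
  best <- .longest_common_substring(gap, dseq, cfg$min_d_match)
  if (best$len != dlen_kept || best$tie) return(FALSE)
  if (best$a_start != d_pos || best$b_start != p$d_trim_5) return(FALSE)
  for (other in d_pool) {
    if (identical(other, dseq)) next
    o <- .longest_common_substring(gap, other, cfg$min_d_match)
    if (o$len >= dlen_kept) return(FALSE)
  }
  # D-side P boundaries
  region1 <- paste0(p$p_v, p$n1, p$p_d5)               # left of D
  region2 <- paste0(p$p_d3, p$n2, p$p_j)               # right of D
  if (p$d_trim_5 == 0L) {
    if (.greedy_p_len(p$dpart, .rev_chars(region1), cfg$p_maxlen) !=
        nchar(p$p_d5)) return(FALSE)
  } else {
    tail_d5 <- .rev_chars(substr(dseq, 1L, p$d_trim_5))
    if (.extends_alignment(tail_d5, .rev_chars(region1))) return(FALSE)
  }
  if (p$d_trim_3 == 0L) {
    if (.greedy_p_len(.rev_chars(p$dpart), region2, cfg$p_maxlen) !=
        nchar(p$p_d3)) return(FALSE)
  } else {
    tail_d3 <- substr(dseq, nchar(dseq) - p$d_trim_3 + 1L, nchar(dseq))
    if (.extends_alignment(tail_d3, region2)) return(FALSE)
  }
  TRUE
}

#' Simulate one V(D)J rearrangement
#'
#' Samples segments per the configured usage, trims junction-facing ends,
#' adds P and N nucleotides, and assembles
#' `V + P? + N1 + P? + D + P? + N2 + P? + J` (IGH) or `V + P? + N1 + P? + J`
#' (IGK). P nucleotides occur only at untrimmed ends, as reverse-complement
#' palindromic extensions of the terminal germline bases. Junctions whose
#' maximal-match decomposition differs from the sampled one are resampled so
#' the returned truth record is always canonical (see the package vignette).
#' Consumes the R RNG stream of the caller; no somatic mutation is applied
#' here.
#'
#' @param db A `germline_db`.
#' @param config A `sim_config`.
#' @return List with `sequence` (read string) and `truth` (one-row
#'   data.frame of the junction ground truth).
#' @export
simulate_rearrangement <- function(db, config) {
  stopifnot(inherits(db, "germline_db"), inherits(config, "sim_config"))
  locus <- config$locus
  vu <- .usage_or_uniform(config$v_usage, db, locus, "V")
  ju <- .usage_or_uniform(config$j_usage, db, locus, "J")
  has_d <- locus == "IGH"
  du <- if (has_d) .usage_or_uniform(config$d_usage, db, locus, "D") else NULL
  d_pool <- if (has_d) unname(db$sequences[segments(db, locus, "D")$id]) else NULL

  # N lengths are sampled once per rearrangement, outside the canonicality
  # loop, so their configured geometric marginal is preserved exactly;
  # trims and P decisions are resampled on conflict instead (see vignette).
  n1_len <- .rgeom1(config$n_mean)
  n2_len <- if (has_d) .rgeom1(config$n_mean) else 0L
  attempts <- 0L
  repeat {
    # resample the segment triple initially and whenever a combination
    # keeps producing non-canonical junctions (possible for degenerate
    # junction settings, e.g. all-zero trims and inserts)
    if (attempts %% 50L == 0L) {
      v_id <- sample(names(vu), 1L, prob = vu)
      j_id <- sample(names(ju), 1L, prob = ju)
      d_id <- if (has_d) sample(names(du), 1L, prob = du) else NA_character_
      vseq <- germline_sequence(db, v_id)
      jseq <- germline_sequence(db, j_id)
      dseq <- if (has_d) germline_sequence(db, d_id) else NULL
    }
    attempts <- attempts + 1L
    if (attempts > 400L) {          # last-resort escape for degenerate
      n1_len <- .rgeom1(config$n_mean)   # segment/length combinations
      n2_len <- if (has_d) .rgeom1(config$n_mean) else 0L
      attempts <- 1L
    }
    v_trim <- .rgeom1(config$trim_mean)
    while (v_trim >= nchar(vseq)) v_trim <- .rgeom1(config$trim_mean)
    j_trim <- .rgeom1(config$trim_mean)
    while (j_trim >= nchar(jseq)) j_trim <- .rgeom1(config$trim_mean)
    if (has_d) {
      repeat {
        d_trim_5 <- .rgeom1(config$trim_mean)
        d_trim_3 <- .rgeom1(config$trim_mean)
        if (d_trim_5 + d_trim_3 < nchar(dseq)) break
      }
    } else d_trim_5 <- d_trim_3 <- 0L

    vpart <- substr(vseq, 1L, nchar(vseq) - v_trim)
    jpart <- substr(jseq, j_trim + 1L, nchar(jseq))
    dpart <- if (has_d) substr(dseq, d_trim_5 + 1L, nchar(dseq) - d_trim_3) else ""

    k <- if (v_trim == 0L) .sample_p_len(config$p_prob, config$p_maxlen) else 0L
    p_v <- if (k > 0L) .revcomp(substr(vseq, nchar(vseq) - k + 1L, nchar(vseq))) else ""
    k <- if (j_trim == 0L) .sample_p_len(config$p_prob, config$p_maxlen) else 0L
    p_j <- if (k > 0L) .revcomp(substr(jseq, 1L, k)) else ""
    if (has_d) {
      k <- if (d_trim_5 == 0L) .sample_p_len(config$p_prob, config$p_maxlen) else 0L
      p_d5 <- if (k > 0L) .revcomp(substr(dseq, 1L, k)) else ""
      k <- if (d_trim_3 == 0L) .sample_p_len(config$p_prob, config$p_maxlen) else 0L
      p_d3 <- if (k > 0L) .revcomp(substr(dseq, nchar(dseq) - k + 1L, nchar(dseq))) else ""
    } else p_d5 <- p_d3 <- ""

    # Resample only the N contents while the junction skeleton (trims, P
    # and N lengths) stays fixed: canonicality conditioning then leaves the
    # configured trim/N length distributions intact. Skeletons whose
    # deterministic pieces conflict are resampled wholesale (rare).
    ok <- FALSE
    for (try in 1:30) {
      n1 <- .rand_bases(n1_len)
      n2 <- if (has_d) .rand_bases(n2_len) else ""
      parts <- list(v_trim = v_trim, j_trim = j_trim,
                    d_trim_5 = d_trim_5, d_trim_3 = d_trim_3,
                    p_v = p_v, p_d5 = p_d5, p_d3 = p_d3, p_j = p_j,
                    n1 = n1, n2 = n2, dpart = dpart)
      if (.junction_canonical(parts, vseq, dseq, jseq, d_pool, config)) {
        ok <- TRUE
        break
      }
      if (n1_len + n2_len == 0L) break   # content-free: conflict is structural
    }
    if (ok) break
  }

  sequence <- paste0(vpart, p_v, n1, p_d5, dpart, p_d3, n2, p_j, jpart)
  truth <- data.frame(
    read_id = NA_character_, lineage_id = NA_character_,
    v_call = v_id, d_call = d_id, j_call = j_id,
    v_trim = parts$v_trim, d_trim_5 = if (has_d) parts$d_trim_5 else NA_integer_,
    d_trim_3 = if (has_d) parts$d_trim_3 else NA_integer_,
    j_trim = parts$j_trim,
    p_v_length = nchar(p_v), p_d5_length = if (has_d) nchar(p_d5) else NA_integer_,
    p_d3_length = if (has_d) nchar(p_d3) else NA_integer_,
    p_j_length = nchar(p_j),
    n1_seq = n1, n2_seq = if (has_d) n2 else NA_character_,
    mutation_positions = "", mutations = "",
    sequence = sequence, stringsAsFactors = FALSE)
  list(sequence = sequence, truth = truth)
}

#' Apply somatic hypermutation to a sequence
#'
#' Each position mutates independently with probability `shm_rate`
#' (`shm_rate * hotspot_multiplier`, capped at 1, inside the CDR mask) to a
#' uniformly chosen different base. Consumes the caller's RNG stream.
#'
#' @param sequence Nucleotide string.
#' @param cdr_mask Logical vector of the same length flagging CDR positions.
#' @param shm_rate Per-base substitution probability.
#' @param hotspot_multiplier Rate multiplier inside the mask.
#' @return List with `sequence` (mutated string) and `positions`
#'   (0-based mutated positions, ascending).
#' @export
apply_shm <- function(sequence, cdr_mask, shm_rate, hotspot_multiplier = 1) {
  n <- nchar(sequence)
  stopifnot(length(cdr_mask) == n)
  if (shm_rate == 0 || n == 0L)
    return(list(sequence = sequence, positions = integer(0)))
  p <- ifelse(cdr_mask, pmin(1, shm_rate * hotspot_multiplier), shm_rate)
  hit <- which(stats::runif(n) < p)
  if (!length(hit)) return(list(sequence = sequence, positions = integer(0)))
  chars <- strsplit(sequence, "")[[1]]
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  list(sequence = paste(chars, collapse = ""), positions = hit - 1L)
}

# CDR mask on an assembled read: germline CDR1/CDR2 intervals (V is always
# complete at its 5' end, so germline V coordinates equal read coordinates
# over the kept V) plus the CDR3 junction span from the V anchor to the end
# of the J anchor codon.
#' @noRd
.read_cdr_mask <- function(read_len, vmeta, v_kept, jmeta, j_trim, j_part_len) {
  mask <- rep(FALSE, read_len)
  mark <- function(mask, s, e) {            # 0-based half-open
    s <- max(0L, s); e <- min(read_len, e)
    if (e > s) mask[(s + 1L):e] <- TRUE
    mask
  }
  if (!is.na(vmeta$cdr1_start))
    mask <- mark(mask, min(vmeta$cdr1_start, v_kept), min(vmeta$cdr1_end, v_kept))
  if (!is.na(vmeta$cdr2_start))
    mask <- mark(mask, min(vmeta$cdr2_start, v_kept), min(vmeta$cdr2_end, v_kept))
  j_anchor_read <- read_len - j_part_len + (jmeta$anchor_offset - j_trim)
  mask <- mark(mask, vmeta$anchor_offset, j_anchor_read + 3L)
  mask
}

#' Simulate a full repertoire with known ground truth
#'
#' Generates `n_reads` annotated-read ground truths. Without lineages every
#' read is an independent rearrangement plus SHM; with `n_lineages`, founder
#' rearrangements are expanded into clonal copies, each copy mutated
#' independently from its founder, sharing a `lineage_id`. Seeded from
#' `config$seed`, so identical configurations reproduce byte-identical
#' output.
#'
#' @param db A `germline_db`.
#' @param config A `sim_config`.
#' @return Object of class `sim_repertoire`: list with `reads` (named
#'   character vector) and `truth` (data.frame, one row per read).
#' @export
simulate_repertoire <- function(db, config) {
  stopifnot(inherits(db, "germline_db"), inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  if (is.null(config$n_lineages)) {
    founder_of <- seq_len(n)
    n_founders <- n
    lineage_ids <- rep(NA_character_, n)
  } else {
    n_founders <- config$n_lineages
    if (!is.null(config$expansion_copies)) {
      copies <- rep(config$expansion_copies, n_founders)
      n <- sum(copies)
    } else {
      copies <- as.integer(stats::rmultinom(1L, n,
                                            rep(1 / n_founders, n_founders)))
      while (any(copies == 0L))
        copies <- as.integer(stats::rmultinom(1L, n,
                                              rep(1 / n_founders, n_founders)))
    }
    founder_of <- rep(seq_len(n_founders), copies)
    lineage_ids <- sprintf("L%03d", founder_of)
  }

  founders <- vector("list", n_founders)
  masks <- vector("list", n_founders)
  for (i in seq_len(n_founders)) {
    founders[[i]] <- simulate_rearrangement(db, config)
    tr <- founders[[i]]$truth
    vmeta <- .segment_meta(db, tr$v_call)
    jmeta <- .segment_meta(db, tr$j_call)
    v_kept <- nchar(db$sequences[[tr$v_call]]) - tr$v_trim
    j_part_len <- nchar(db$sequences[[tr$j_call]]) - tr$j_trim
    masks[[i]] <- .read_cdr_mask(nchar(founders[[i]]$sequence), vmeta,
                                 v_kept, jmeta, tr$j_trim, j_part_len)
  }

  reads <- character(n)
  truth <- vector("list", n)
  for (r in seq_len(n)) {
    f <- founder_of[r]
    base <- founders[[f]]
    mut <- apply_shm(base$sequence, masks[[f]], config$shm_rate,
                     config$hotspot_multiplier)
    tr <- base$truth
    tr$read_id <- sprintf("read_%06d", r)
    tr$lineage_id <- lineage_ids[r]
    tr$sequence <- mut$sequence
    tr$mutation_positions <- paste(mut$positions, collapse = ",")
    if (length(mut$positions)) {
      from <- substring(base$sequence, mut$positions + 1L, mut$positions + 1L)
      to <- substring(mut$sequence, mut$positions + 1L, mut$positions + 1L)
      tr$mutations <- paste(sprintf("%d%s>%s", mut$positions, from, to),
                            collapse = ",")
    }
    reads[r] <- mut$sequence
    truth[[r]] <- tr
  }
  truth <- do.call(rbind, truth)
  names(reads) <- truth$read_id
  rownames(truth) <- NULL
  structure(list(reads = reads, truth = truth, config = config),
            class = "sim_repertoire")
}

#' @export
print.sim_repertoire <- function(x, ...) {
  cat("sim_repertoire:", length(x$reads), "reads,",
      x$config$locus, "locus")
  if (!is.null(x$config$n_lineages))
    cat(",", x$config$n_lineages, "clonal lineages")
  cat("\n")
  invisible(x)
}

#' Reconstruct a read from its truth record
#'
#' Rebuilds the emitted read string from the junction ground truth (segment
#' ids, trims, P lengths, N strings, substitution list) and the germline
#' database. Used to verify that truth records fully determine the reads.
#'
#' @param truth_row One row of a `sim_repertoire` truth table.
#' @param db The `germline_db` used for simulation.
#' @return The reconstructed read string.
#' @export
reconstruct_read <- function(truth_row, db) {
  stopifnot(nrow(truth_row) == 1L)
  vseq <- germline_sequence(db, truth_row$v_call)
  jseq <- germline_sequence(db, truth_row$j_call)
  has_d <- !is.na(truth_row$d_call)
  vpart <- substr(vseq, 1L, nchar(vseq) - truth_row$v_trim)
  jpart <- substr(jseq, truth_row$j_trim + 1L, nchar(jseq))
  p_of_3end <- function(s, k) if (k > 0L)
    .revcomp(substr(s, nchar(s) - k + 1L, nchar(s))) else ""
  p_of_5end <- function(s, k) if (k > 0L) .revcomp(substr(s, 1L, k)) else ""
  p_v <- p_of_3end(vseq, truth_row$p_v_length)
  p_j <- p_of_5end(jseq, truth_row$p_j_length)
  if (has_d) {
    dseq <- germline_sequence(db, truth_row$d_call)
    dpart <- substr(dseq, truth_row$d_trim_5 + 1L,
                    nchar(dseq) - truth_row$d_trim_3)
    p_d5 <- p_of_5end(dseq, truth_row$p_d5_length)
    p_d3 <- p_of_3end(dseq, truth_row$p_d3_length)
    n2 <- truth_row$n2_seq
  } else {
    dpart <- p_d5 <- p_d3 <- n2 <- ""
  }
  s <- paste0(vpart, p_v, truth_row$n1_seq, p_d5, dpart, p_d3, n2, p_j, jpart)
  if (nzchar(truth_row$mutations)) {
    for (m in strsplit(truth_row$mutations, ",", fixed = TRUE)[[1]]) {
      pos <- as.integer(sub("^([0-9]+).*$", "\\1", m))
      to <- sub("^[0-9]+[ACGT]>([ACGT])$", "\\1", m)
      substr(s, pos + 1L, pos + 1L) <- to
    }
  }
  s
}

#' Write a simulated repertoire to disk
#'
#' Writes reads as FASTA (`<prefix>.fasta`) and the truth table as TSV
#' (`<prefix>_truth.tsv`).
#'
#' @param x A `sim_repertoire`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_repertoire <- function(x, prefix) {
  stopifnot(inherits(x, "sim_repertoire"))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_truth.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$reads), fa)
  utils::write.table(x$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, tsv))
}
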