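# Germline assignment, junction decomposition, CDR3 extraction and
# productivity calling. A deterministic, desk-scale stand-in for IgBlast:
# gapless local alignment (match +1 / mismatch -1), lexicographic
# tie-breaking, greedy maximal P before N.

#' @noRd
.NUC_MAT <- NULL

#' @noRd
.nuc_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# Gapless local alignment of many reads against one subject.
# Returns a data.frame of scores and 0-based half-open intervals.
#' @noRd
.align_local <- function(reads, subject_seq) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(subject_seq),
    type = "local", substitutionMatrix = .nuc_mat(),
    gapOpening = 1e5, gapExtension = 1e5)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  data.frame(score = BiocGenerics::score(aln),
             nmatch = Biostrings::nmatch(aln),
             p_start = BiocGenerics::start(pr) - 1L,
             p_end = BiocGenerics::end(pr),
             s_start = BiocGenerics::start(sr) - 1L,
             s_end = BiocGenerics::end(sr))
}

# Best segment per read over a candidate set, iterated in id order so that
# score ties resolve to the lexicographically smallest id (flagged).
#' @noRd
.best_segment <- function(reads, ids, seqs) {
  n <- length(reads)
  best <- data.frame(call = rep(NA_character_, n), score = rep(-Inf, n),
                     nmatch = NA_integer_, p_start = NA_integer_,
                     p_end = NA_integer_, s_start = NA_integer_,
                     s_end = NA_integer_, tie = rep(FALSE, n))
  nonempty <- which(nchar(reads) > 0L)
  if (!length(nonempty)) return(best)
  for (id in ids) {
    a <- .align_local(reads[nonempty], seqs[[id]])
    better <- a$score > best$score[nonempty]
    equal <- a$score == best$score[nonempty]
    best$tie[nonempty[equal]] <- TRUE
    idx <- nonempty[better]
    best$call[idx] <- id
    best$score[idx] <- a$score[better]
    best$nmatch[idx] <- a$nmatch[better]
    best$p_start[idx] <- a$p_start[better]
    best$p_end[idx] <- a$p_end[better]
    best$s_start[idx] <- a$s_start[better]
    best$s_end[idx] <- a$s_end[better]
    best$tie[idx] <- FALSE
  }
  best
}

# Greedy maximal P, then N: split an inter-segment region into
# (P_left, N, P_right). `left_end_bases` ordered outward from the left
# segment's end (or NULL when that end is trimmed); likewise `right_start`.
#' @noRd
.split_pn <- function(region, left_end_bases, right_start_bases, p_maxlen) {
  pl <- if (is.null(left_end_bases)) 0L
        else .greedy_p_len(left_end_bases, region, p_maxlen)
  rest <- substr(region, pl + 1L, nchar(region))
  pr <- if (is.null(right_start_bases)) 0L
        else .greedy_p_len(right_start_bases, .rev_chars(rest), p_maxlen)
  n_seq <- substr(rest, 1L, nchar(rest) - pr)
  list(p_left = pl, n = n_seq, p_right = pr)
}

#' Annotate repertoire reads against a germline reference
#'
#' Assigns V, (D,) and J germline segments by gapless local alignment
#' identity, decomposes the junction into trims, P and N additions, extracts
#' CDR1/2/3 amino-acid sequences using the conserved Cys104 / Phe-Trp118
#' anchors, calls productivity, and lists V-region point mutations against
#' the germline. Output follows AIRR rearrangement naming where columns
#' exist there; all coordinates are 0-based half-open. The CDR3 convention
#' (Cys104 included, J anchor excluded; `junction` includes both anchor
#' codons) is recorded in the `cdr3_definition` attribute.
#'
#' V is chosen first over the whole read; J over the region downstream of
#' the V; D (IGH only) as the longest exact germline substring of the V-J
#' gap, `"unassigned"` (NA) below `min_d_match` consecutive matching bases.
#' Segment-score ties break to the lexicographically smallest id and are
#' flagged. Reads whose best V falls below `min_v_identity` over at least
#' `min_v_length` aligned bases are excluded and counted in the `qc`
#' attribute.
#'
#' @param reads Named character vector of nucleotide reads, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param db A `germline_db`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param min_v_identity Minimum V alignment identity (default 0.7).
#' @param min_v_length Minimum aligned V span in nt (default 50).
#' @param min_d_match Minimum consecutive matching bases to call D
#'   (default 5).
#' @param p_maxlen Maximum P-nucleotide length considered (default 4).
#' @param duplicate_count Optional integer vector of per-read copy numbers
#'   (default all 1).
#' @return A data.frame (one row per annotatable read) with attributes
#'   `qc` (input/excluded counts) and `cdr3_definition`.
#' @export
annotate_reads <- function(reads, db, locus = c("IGH", "IGK"),
                           min_v_identity = 0.7, min_v_length = 50L,
                           min_d_match = 5L, p_maxlen = 4L,
                           duplicate_count = NULL) {
  locus <- match.arg(locus)
  stopifnot(inherits(db, "germline_db"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]+$", reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  if (is.null(duplicate_count)) duplicate_count <- rep(1L, length(reads))
  stopifnot(length(duplicate_count) == length(reads))

  vmeta_all <- segments(db, locus, "V")
  jmeta_all <- segments(db, locus, "J")
  if (!nrow(vmeta_all) || !nrow(jmeta_all))
    stop("germline db has no ", locus, " V/J segments", call. = FALSE)
  has_d <- locus == "IGH"
  dmeta_all <- if (has_d) segments(db, locus, "D") else NULL

  n <- length(reads)
  v <- .best_segment(reads, vmeta_all$id, db$sequences)
  v_ident <- v$nmatch / pmax(1L, v$p_end - v$p_start)
  annotatable <- !is.na(v$call) & v_ident >= min_v_identity &
    (v$p_end - v$p_start) >= min_v_length
  qc <- list(n_input = n, n_unannotatable = sum(!annotatable),
             unannotatable_ids = names(reads)[!annotatable])

  keep <- which(annotatable)
  reads_k <- reads[keep]
  v <- v[keep, , drop = FALSE]
  dup_k <- duplicate_count[keep]
  nk <- length(keep)

  suffixes <- substr(reads_k, v$p_end + 1L, nchar(reads_k))
  j <- .best_segment(suffixes, jmeta_all$id, db$sequences)
  # back to read coordinates
  j$p_start <- j$p_start + v$p_end
  j$p_end <- j$p_end + v$p_end
  j_ok <- !is.na(j$call) & (j$p_end - j$p_start) >= 12L &
    j$nmatch / pmax(1L, j$p_end - j$p_start) >= 0.7

  out <- vector("list", nk)
  for (i in seq_len(nk)) {
    read <- reads_k[[i]]
    v_id <- v$call[i]
    vseq <- db$sequences[[v_id]]
    vmeta <- vmeta_all[vmeta_all$id == v_id, ]
    v_trim <- nchar(vseq) - v$s_end[i]
    row <- list(
      sequence_id = names(reads_k)[i], sequence = read, locus = locus,
      v_call = v_id, d_call = NA_character_,
      j_call = if (j_ok[i]) j$call[i] else NA_character_,
      v_identity = round(100 * v$nmatch[i] / (v$p_end[i] - v$p_start[i]), 4),
      v_start = v$p_start[i], v_end = v$p_end[i],
      v_germline_start = v$s_start[i], v_germline_end = v$s_end[i],
      d_start = NA_integer_, d_end = NA_integer_,
      d_germline_start = NA_integer_, d_germline_end = NA_integer_,
      j_start = NA_integer_, j_end = NA_integer_,
      j_germline_start = NA_integer_, j_germline_end = NA_integer_,
      v_trim = v_trim, d_trim_5 = NA_integer_, d_trim_3 = NA_integer_,
      j_trim = NA_integer_,
      p_v_length = NA_integer_, p_d5_length = NA_integer_,
      p_d3_length = NA_integer_, p_j_length = NA_integer_,
      n1 = NA_character_, n2 = NA_character_,
      n1_length = NA_integer_, n2_length = NA_integer_,
      np1_length = NA_integer_, np2_length = NA_integer_,
      junction = NA_character_, junction_aa = NA_character_,
      cdr3 = NA_character_, cdr3_aa = NA_character_,
      cdr1_aa = NA_character_, cdr2_aa = NA_character_,
      vj_in_frame = NA, productive = FALSE, cdr3_unresolved = TRUE,
      v_tie = v$tie[i], d_tie = FALSE,
      v_mutations = "", v_mutation_count = 0L,
      duplicate_count = dup_k[i])

    # V mutations on germline coordinates (gapless alignment)
    gl <- strsplit(substr(vseq, v$s_start[i] + 1L, v$s_end[i]), "")[[1]]
    rd <- strsplit(substr(read, v$p_start[i] + 1L, v$p_end[i]), "")[[1]]
    mm <- which(gl != rd)
    if (length(mm)) {
      pos <- v$s_start[i] + mm - 1L
      row$v_mutations <- paste(sprintf("%d%s>%s", pos, gl[mm], rd[mm]),
                               collapse = ",")
      row$v_mutation_count <- length(mm)
    }

    # CDR1/CDR2 amino acids from germline intervals mapped onto the read
    map_aa <- function(gs, ge) {
      if (is.na(gs) || gs < v$s_start[i] || ge > v$s_end[i])
        return(NA_character_)
      rs <- v$p_start[i] + (gs - v$s_start[i])
      .translate_nt(substr(read, rs + 1L, rs + (ge - gs)))
    }
    row$cdr1_aa <- map_aa(vmeta$cdr1_start, vmeta$cdr1_end)
    row$cdr2_aa <- map_aa(vmeta$cdr2_start, vmeta$cdr2_end)

    if (j_ok[i]) {
      j_id <- j$call[i]
      jseq <- db$sequences[[j_id]]
      jmeta <- jmeta_all[jmeta_all$id == j_id, ]
      row$j_start <- j$p_start[i]; row$j_end <- j$p_end[i]
      row$j_germline_start <- j$s_start[i]; row$j_germline_end <- j$s_end[i]
      j_trim <- j$s_start[i]
      row$j_trim <- j_trim

      gap_start <- v$p_end[i]; gap_end <- j$p_start[i]
      gap <- substr(read, gap_start + 1L, gap_end)

      # --- D assignment (IGH): longest exact germline substring of the gap
      if (has_d && nchar(gap) >= min_d_match) {
        best_len <- 0L; best_d <- NULL
        for (did in dmeta_all$id) {
          lcs <- .longest_common_substring(gap, db$sequences[[did]],
                                           min_d_match)
          if (lcs$len > best_len) {
            best_len <- lcs$len
            best_d <- list(id = did, lcs = lcs)
            row$d_tie <- FALSE
          } else if (lcs$len == best_len && best_len > 0L) row$d_tie <- TRUE
        }
        if (!is.null(best_d)) {
          dseq <- db$sequences[[best_d$id]]
          row$d_call <- best_d$id
          row$d_start <- gap_start + best_d$lcs$a_start
          row$d_end <- row$d_start + best_d$lcs$len
          row$d_germline_start <- best_d$lcs$b_start
          row$d_germline_end <- best_d$lcs$b_start + best_d$lcs$len
          row$d_trim_5 <- row$d_germline_start
          row$d_trim_3 <- nchar(dseq) - row$d_germline_end
        }
      }

      # --- junction decomposition: P (untrimmed ends only, greedy max) then N
      v_end_bases <- if (v_trim == 0L) .rev_chars(vseq) else NULL
      j_start_bases <- if (j_trim == 0L) jseq else NULL
      if (has_d && !is.na(row$d_call)) {
        dseq <- db$sequences[[row$d_call]]
        dpart <- substr(dseq, row$d_germline_start + 1L, row$d_germline_end)
        region1 <- substr(read, gap_start + 1L, row$d_start)
        region2 <- substr(read, row$d_end + 1L, gap_end)
        s1 <- .split_pn(region1, v_end_bases,
                        if (row$d_trim_5 == 0L) dpart else NULL, p_maxlen)
        s2 <- .split_pn(region2,
                        if (row$d_trim_3 == 0L) .rev_chars(dpart) else NULL,
                        j_start_bases, p_maxlen)
        row$p_v_length <- s1$p_left; row$p_d5_length <- s1$p_right
        row$p_d3_length <- s2$p_left; row$p_j_length <- s2$p_right
        row$n1 <- s1$n; row$n2 <- s2$n
        row$n1_length <- nchar(s1$n); row$n2_length <- nchar(s2$n)
        row$np1_length <- nchar(region1); row$np2_length <- nchar(region2)
      } else {
        s1 <- .split_pn(gap, v_end_bases, j_start_bases, p_maxlen)
        row$p_v_length <- s1$p_left; row$p_j_length <- s1$p_right
        row$n1 <- s1$n; row$n1_length <- nchar(s1$n)
        row$np1_length <- nchar(gap)
        if (!has_d) { row$n2 <- NA_character_ }
      }

      # --- CDR3 via anchors
      va <- vmeta$anchor_offset; ja <- jmeta$anchor_offset
      v_anchor_ok <- va >= v$s_start[i] && (va + 3L) <= v$s_end[i]
      j_anchor_ok <- ja >= j$s_start[i] && (ja + 3L) <= j$s_end[i]
      if (v_anchor_ok && j_anchor_ok) {
        v_anchor_read <- v$p_start[i] + (va - v$s_start[i])
        j_anchor_read <- j$p_start[i] + (ja - j$s_start[i])
        anchor_c <- .translate_nt(substr(read, v_anchor_read + 1L,
                                         v_anchor_read + 3L))
        anchor_fw <- .translate_nt(substr(read, j_anchor_read + 1L,
                                          j_anchor_read + 3L))
        if (anchor_c == "C" && anchor_fw %in% c("F", "W")) {
          row$cdr3_unresolved <- FALSE
          row$cdr3 <- substr(read, v_anchor_read + 1L, j_anchor_read)
          row$junction <- substr(read, v_anchor_read + 1L, j_anchor_read + 3L)
          in_frame <- (j_anchor_read - v_anchor_read) %% 3L == 0L
          row$vj_in_frame <- in_frame
          if (in_frame) {
            row$cdr3_aa <- .translate_nt(row$cdr3)
            row$junction_aa <- .translate_nt(row$junction)
          } else row$cdr3_aa <- ""
          # productive: in frame and stop-free over the aligned V..J span
          if (in_frame) {
            rf <- vmeta$reading_frame
            p0 <- v$p_start[i] + ((rf - v$s_start[i]) %% 3L)
            span <- substr(read, p0 + 1L, j$p_end[i])
            aa <- .translate_nt(span)
            row$productive <- !grepl("*", aa, fixed = TRUE)
          }
        }
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(res)) res <- .empty_rearrangement()
  rownames(res) <- NULL
  attr(res, "qc") <- qc
  attr(res, "cdr3_definition") <-
    "cdr3: Cys104 codon (included) to the codon before the J Phe/Trp118 anchor; junction: cdr3 plus both anchor codons"
  res
}

#' @noRd
.empty_rearrangement <- function() {
  data.frame(sequence_id = character(0), sequence = character(0),
             locus = character(0), v_call = character(0),
             d_call = character(0), j_call = character(0),
             stringsAsFactors = FALSE)
}
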