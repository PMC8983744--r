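#' Load a germline gene-segment reference
#'
#' Reads germline V, D and J segments from a FASTA file together with a
#' tab-separated metadata sidecar and returns a validated germline database.
#' The metadata carries, per segment, the locus (`IGH` or `IGK`), the segment
#' type (`V`, `D` or `J`), an IMGT-like functionality label (`functional`,
#' `ORF` or `pseudogene`), the 0-based offset of the conserved anchor codon
#' (Cys104 for V segments, Phe/Trp118 for J segments; absent for D), the
#' reading frame in `{0,1,2}` for V and J, and optional 0-based half-open
#' CDR1/CDR2 intervals on V segments used for region labelling and
#' hotspot-biased mutation simulation.
#'
#' All coordinates in this package are 0-based, half-open.
#'
#' @param fasta_path Path to a FASTA file of nucleotide segment sequences;
#'   record ids must match the metadata `id` column one-to-one.
#' @param metadata_path Path to a TSV with columns `id`, `locus`,
#'   `segment_type`, `functionality`, `anchor_offset`, `reading_frame` and
#'   optionally `cdr1_start`, `cdr1_end`, `cdr2_start`, `cdr2_end`.
#' @return An object of class `germline_db`: a list with elements
#'   `segments` (metadata data.frame, id-sorted) and `sequences`
#'   (named character vector).
#' @examples
#' fa <- system.file("extdata", "toy_germline.fasta", package = "vdjrep")
#' md <- system.file("extdata", "toy_germline_metadata.tsv", package = "vdjrep")
#' db <- load_germline(fa, md)
#' db
#' @export
load_germline <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  # keep only the first whitespace-delimited token of each FASTA header
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate segment id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("id", "locus", "segment_type", "functionality",
                "anchor_offset", "reading_frame")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("cdr1_start", "cdr1_end", "cdr2_start", "cdr2_end"))
    if (!cc %in% names(meta)) meta[[cc]] <- NA_integer_
  if (anyDuplicated(meta$id))
    stop("duplicate segment id(s) in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  orphans_fa <- setdiff(ids, meta$id)
  orphans_md <- setdiff(meta$id, ids)
  if (length(orphans_fa) || length(orphans_md))
    stop("FASTA/metadata mismatch; FASTA-only: [",
         paste(orphans_fa, collapse = ", "), "], metadata-only: [",
         paste(orphans_md, collapse = ", "), "]", call. = FALSE)

  sequences <- toupper(as.character(seqs))
  names(sequences) <- ids
  ord <- order(meta$id, method = "radix")
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  sequences <- sequences[meta$id]

  .validate_segments(meta, sequences)
  structure(list(segments = meta, sequences = sequences),
            class = "germline_db")
}

#' @noRd
.validate_segments <- function(meta, sequences) {
  if (any(!meta$locus %in% c("IGH", "IGK")))
    stop("locus must be IGH or IGK", call. = FALSE)
  if (any(!meta$segment_type %in% c("V", "D", "J")))
    stop("segment_type must be V, D or J", call. = FALSE)
  if (any(!meta$functionality %in% c("functional", "ORF", "pseudogene")))
    stop("functionality must be functional, ORF or pseudogene", call. = FALSE)
  if (any(nchar(sequences) == 0L))
    stop("empty sequence(s)", call. = FALSE)
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences must be over {A,C,G,T}", call. = FALSE)
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    s <- sequences[[i]]
    if (m$segment_type %in% c("V", "J")) {
      if (is.na(m$anchor_offset))
        stop("segment ", m$id, ": V/J segments require anchor_offset",
             call. = FALSE)
      if (m$anchor_offset < 0L || m$anchor_offset > nchar(s) - 3L)
        stop("segment ", m$id, ": anchor_offset outside sequence",
             call. = FALSE)
      if (is.na(m$reading_frame) || !m$reading_frame %in% 0:2)
        stop("segment ", m$id, ": reading_frame must be in {0,1,2}",
             call. = FALSE)
      anchor_aa <- .translate_nt(substr(s, m$anchor_offset + 1L,
                                        m$anchor_offset + 3L))
      if (m$segment_type == "V" && anchor_aa != "C")
        stop("segment ", m$id, ": V anchor codon '",
             substr(s, m$anchor_offset + 1L, m$anchor_offset + 3L),
             "' does not encode Cys", call. = FALSE)
      if (m$segment_type == "J" && !anchor_aa %in% c("F", "W"))
        stop("segment ", m$id, ": J anchor codon does not encode Phe/Trp",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.germline_db <- function(x, ...) {
  tab <- table(x$segments$locus, x$segments$segment_type)
  cat("germline_db:", nrow(x$segments), "segments\n")
  print(tab)
  invisible(x)
}

#' Query germline segments by locus and type
#'
#' @param db A `germline_db`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param segment_type `"V"`, `"D"` or `"J"`.
#' @return Metadata data.frame of matching segments, id-sorted (deterministic).
#' @export
segments <- function(db, locus, segment_type) {
  stopifnot(inherits(db, "germline_db"))
  if (!locus %in% c("IGH", "IGK")) stop("unknown locus: ", locus, call. = FALSE)
  if (!segment_type %in% c("V", "D", "J"))
    stop("unknown segment_type: ", segment_type, call. = FALSE)
  out <- db$segments[db$segments$locus == locus &
                     db$segments$segment_type == segment_type, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional germline segments
#'
#' Returns the segments of a given locus and type whose functionality label
#' passes the filter. With an IMGT-annotated human IGHV reference this
#' recovers the full set of functional V genes. Whether "potentially
#' functional" sets should include ORF-labelled segments varies by analysis,
#' so ORF inclusion is a switch.
#'
#' @inheritParams segments
#' @param include_orf Also keep segments labelled `ORF` (default `FALSE`).
#' @return Metadata data.frame, id-sorted.
#' @export
functional_segments <- function(db, locus, segment_type, include_orf = FALSE) {
  out <- segments(db, locus, segment_type)
  keep <- c("functional", if (include_orf) "ORF")
  out <- out[out$functionality %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retrieve a germline sequence by id
#'
#' @param db A `germline_db`.
#' @param id Segment id.
#' @return Nucleotide string.
#' @export
germline_sequence <- function(db, id) {
  stopifnot(inherits(db, "germline_db"))
  if (!id %in% names(db$sequences)) stop("unknown segment id: ", id, call. = FALSE)
  unname(db$sequences[[id]])
}

#' @noRd
.segment_meta <- function(db, id) {
  i <- match(id, db$segments$id)
  if (is.na(i)) stop("unknown segment id: ", id, call. = FALSE)
  db$segments[i, , drop = FALSE]
}

#' Bundled toy germline database
#'
#' Convenience loader for the small synthetic germline reference shipped with
#' the package (4 functional + 1 pseudogene IGHV, 3 IGHD, 2 IGHJ, 3 IGKV,
#' 2 IGKJ). The sequences are synthetic, generated for testing and the demo
#' pipeline; they are not IMGT alleles.
#'
#' @return A `germline_db`.
#' @export
toy_germline <- function() {
  load_germline(
    system.file("extdata", "toy_germline.fasta", package = "vdjrep"),
    system.file("extdata", "toy_germline_metadata.tsv", package = "vdjrep"))
}
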