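# Readers/writers for the rearrangement-table dialect. Column names follow
# the AIRR rearrangement schema where a column exists there; package-specific
# columns (junction decomposition details, tie flags) keep their own names.
# All coordinates are 0-based half-open.

# type map for the columns this package writes; unknown columns pass
# through as character
#' @noRd
.REARR_TYPES <- c(
  sequence_id = "character", sequence = "character", locus = "character",
  v_call = "character", d_call = "character", j_call = "character",
  v_identity = "numeric",
  v_start = "integer", v_end = "integer",
  v_germline_start = "integer", v_germline_end = "integer",
  d_start = "integer", d_end = "integer",
  d_germline_start = "integer", d_germline_end = "integer",
  j_start = "integer", j_end = "integer",
  j_germline_start = "integer", j_germline_end = "integer",
  v_trim = "integer", d_trim_5 = "integer", d_trim_3 = "integer",
  j_trim = "integer",
  p_v_length = "integer", p_d5_length = "integer", p_d3_length = "integer",
  p_j_length = "integer",
  n1 = "character", n2 = "character",
  n1_length = "integer", n2_length = "integer",
  np1_length = "integer", np2_length = "integer",
  junction = "character", junction_aa = "character",
  cdr3 = "character", cdr3_aa = "character",
  cdr1_aa = "character", cdr2_aa = "character",
  vj_in_frame = "logical", productive = "logical",
  cdr3_unresolved = "logical", v_tie = "logical", d_tie = "logical",
  v_mutations = "character", v_mutation_count = "integer",
  duplicate_count = "integer")

#' Write a rearrangement table as TSV
#'
#' Tab-separated, no quoting or comments; `NA` is written as the literal
#' `NA` so that empty strings (e.g. a zero-length N region) survive the
#' round trip. The schema is carried in a sidecar JSON
#' (`<path>.schema.json`).
#'
#' @param tab Annotated rearrangement data.frame.
#' @param path Output path.
#' @param schema_sidecar Write the sidecar schema file (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_rearrangement_tsv <- function(tab, path, schema_sidecar = TRUE) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (schema_sidecar) {
    types <- vapply(tab, function(col) class(col)[1], character(1))
    jsonlite::write_json(as.list(types), paste0(path, ".schema.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a rearrangement table from TSV
#'
#' Validates the presence of the required columns and restores the column
#' types this package writes; unknown columns are preserved as character.
#' An empty file with a header yields an empty table.
#'
#' @param path Path to a TSV written by [write_rearrangement_tsv()] (or any
#'   AIRR-style rearrangement TSV using the same column names).
#' @param required Columns that must be present (default `sequence_id`,
#'   `v_call`, `j_call`).
#' @return data.frame.
#' @export
read_rearrangement_tsv <- function(path,
                                   required = c("sequence_id", "v_call",
                                                "j_call")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = "character")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("rearrangement TSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in names(tab)) {
    ty <- .REARR_TYPES[col]
    if (is.na(ty)) next
    tab[[col]] <- switch(ty,
      integer = as.integer(tab[[col]]),
      numeric = as.numeric(tab[[col]]),
      logical = as.logical(tab[[col]]),
      tab[[col]])
  }
  tab
}
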