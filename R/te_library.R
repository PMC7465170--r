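#' TE consensus libraries
#'
#' A TE consensus library is a tibble with one row per TE family and columns:
#' \describe{
#'   \item{name}{unique family identifier.}
#'   \item{group}{one of `"DNA"`, `"LINE"`, `"LTR"`.}
#'   \item{sequence}{consensus nucleotide sequence over `{A,C,G,T,N}`,
#'     uppercase.}
#'   \item{tsd_size}{expected target-site-duplication size in nt, or `NA`
#'     when unknown. Known sizes must lie in `[2, 18]` (18 nt is the largest
#'     TSD reported for any LTR element).}
#' }
#'
#' @name te_library
NULL

TE_GROUPS <- c("DNA", "LINE", "LTR")

#' Build a TE consensus library from vectors
#'
#' @param name character vector of unique family names.
#' @param group character vector over `{DNA, LINE, LTR}`.
#' @param sequence character vector of consensus sequences.
#' @param tsd_size integer vector of expected TSD sizes (`NA` = unknown).
#' @return a `te_library` tibble (see [te_library]).
#' @export
#' @examples
#' lib <- te_library_tbl(
#'   name = c("gypsy1", "jockey1"), group = c("LTR", "LINE"),
#'   sequence = c("ACGTACGTAA", "TTGGCCAATT"), tsd_size = c(4L, NA)
#' )
te_library_tbl <- function(name, group, sequence, tsd_size = NA_integer_) {
  lib <- tibble(
    name = as.character(name),
    group = as.character(group),
    sequence = vapply(as.character(sequence), check_seq, "",
                      what = "consensus sequence", USE.NAMES = FALSE),
    tsd_size = as.integer(tsd_size)
  )
  validate_te_library(lib)
}

validate_te_library <- function(lib) {
  if (anyDuplicated(lib$name)) {
    abort(sprintf("duplicate family name: %s",
                  paste(unique(lib$name[duplicated(lib$name)]), collapse = ", ")))
  }
  if (any(!nzchar(lib$name))) abort("family names must be non-empty")
  bad <- setdiff(unique(lib$group), TE_GROUPS)
  if (length(bad)) {
    abort(sprintf("invalid group label(s): %s (must be DNA, LINE or LTR)",
                  paste(bad, collapse = ", ")))
  }
  if (any(nchar(lib$sequence) < 1L)) abort("consensus sequences must be non-empty")
  known <- !is.na(lib$tsd_size)
  if (any(known & (lib$tsd_size < 2L | lib$tsd_size > 18L))) {
    abort("known tsd_size values must lie in [2, 18]")
  }
  class(lib) <- c("te_library", class(tibble()))
  lib
}

#' Load a TE consensus library from FASTA plus annotation table
#'
#' Reads family consensus sequences from `consensus_file` (FASTA) and joins
#' them with a tab-separated annotation table carrying, per family, the TE
#' group (`DNA`, `LINE` or `LTR`) and optionally the expected TSD size in nt.
#' Families without an annotated TSD size get `NA` ("unknown").
#'
#' @param consensus_file path to a FASTA of consensus sequences; record names
#'   (first whitespace-delimited token) are the family names.
#' @param annotation_file path to a TSV with columns `name`, `group` and
#'   optionally `tsd_size`; a header line is expected.
#' @return a `te_library` tibble with one row per FASTA record, in FASTA
#'   order, and a `provenance` attribute recording both paths.
#' @export
load_te_library <- function(consensus_file, annotation_file) {
  seqs <- Biostrings::readDNAStringSet(consensus_file)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate family name in FASTA: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  ann <- readr::read_tsv(annotation_file, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("name", "group") %in% names(ann))) {
    abort("annotation table must have columns 'name' and 'group'")
  }
  missing_seq <- setdiff(ann$name, nm)
  if (length(missing_seq)) {
    abort(sprintf("annotation row(s) without matching FASTA record: %s",
                  paste(missing_seq, collapse = ", ")))
  }
  missing_ann <- setdiff(nm, ann$name)
  if (length(missing_ann)) {
    abort(sprintf("FASTA record(s) without annotation: %s",
                  paste(missing_ann, collapse = ", ")))
  }
  if (!"tsd_size" %in% names(ann)) ann$tsd_size <- NA_integer_
  idx <- match(nm, ann$name)
  lib <- te_library_tbl(
    name = nm,
    group = ann$group[idx],
    sequence = as.character(seqs),
    tsd_size = ann$tsd_size[idx]
  )
  attr(lib, "provenance") <- c(consensus = consensus_file,
                               annotation = annotation_file)
  lib
}

#' Write a TE library back to FASTA + annotation TSV
#'
#' Inverse of [load_te_library()]: reloading the written pair yields an
#' identical library.
#'
#' @param lib a `te_library` tibble.
#' @param consensus_file,annotation_file output paths.
#' @return `lib`, invisibly.
#' @export
write_te_library <- function(lib, consensus_file, annotation_file) {
  seqs <- Biostrings::DNAStringSet(lib$sequence)
  names(seqs) <- lib$name
  Biostrings::writeXStringSet(seqs, consensus_file)
  readr::write_tsv(tibble(name = lib$name, group = lib$group,
                          tsd_size = lib$tsd_size),
                   annotation_file, progress = FALSE)
  invisible(lib)
}

#' LTR subset of a TE library
#'
#' Returns the entries with `group == "LTR"`, order preserved. Idempotent;
#' an empty subset is allowed. MIV validation operates on this subset only.
#'
#' @param lib a `te_library` tibble.
#' @return a `te_library` tibble of the LTR families.
#' @export
ltr_subset <- function(lib) {
  out <- lib[lib$group == "LTR", , drop = FALSE]
  class(out) <- class(lib)
  out
}

#' Default expected TSD sizes for commonly studied LTR families
#'
#' A small editable configuration: ZAM integrates with a 4-nt TSD; the other
#' frequently studied LTR families default to 5 nt. Values can be overridden
#' by the annotation table of [load_te_library()].
#'
#' @return a named integer vector of TSD sizes in nt.
#' @export
default_tsd_sizes <- function() {
  c(ZAM = 4L, gtwin = 5L, roo = 5L, copia = 5L, blood = 5L, mdg3 = 5L)
}
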