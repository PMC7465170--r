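#' Read primary alignment records from SAM/BAM into a tibble
#'
#' Loads mapped, primary alignment records (secondary and supplementary
#' alignments are dropped, since they do not carry the full read sequence)
#' with the fields needed for CIGAR-based structural-variant mining.
#' Reference positions are converted to 0-based.
#'
#' @param path a SAM or BAM file.
#' @param sample_id label attached to every record.
#' @return a tibble with columns `sample_id`, `read_id`, `contig`,
#'   `ref_start` (0-based), `strand`, `cigar`, `seq`.
#' @export
read_alignment_records <- function(path, sample_id = "sample") {
  bam <- ensure_bam(path)
  flt <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flt,
    what = c("qname", "rname", "pos", "strand", "cigar", "seq")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble(
    sample_id = sample_id,
    read_id = x$qname,
    contig = as.character(x$rname),
    ref_start = x$pos - 1L,
    strand = as.character(x$strand),
    cigar = x$cigar,
    seq = as.character(x$seq)
  )
}

#' Read per-mate records of paired-end alignments from SAM/BAM
#'
#' One row per alignment record (both mates), for the discordant-pair TE
#' insertion caller. Unmapped records are kept (with `NA` position) so that
#' mate-pairing logic can see them.
#'
#' @inheritParams read_alignment_records
#' @return a tibble with columns `read_id`, `mate` (1 or 2), `ref`, `pos`
#'   (0-based or `NA`), `strand`, `mapped`, `proper_pair`.
#' @export
read_pair_records <- function(path, sample_id = "sample") {
  bam <- ensure_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- x$flag
  keep <- bitwAnd(flag, 0x900L) == 0L  # primary records only
  flag <- flag[keep]
  tibble(
    sample_id = sample_id,
    read_id = x$qname[keep],
    mate = ifelse(bitwAnd(flag, 0x40L) != 0L, 1L, 2L),
    ref = as.character(x$rname)[keep],
    pos = x$pos[keep] - 1L,
    strand = as.character(x$strand)[keep],
    mapped = bitwAnd(flag, 0x4L) == 0L,
    proper_pair = bitwAnd(flag, 0x2L) != 0L
  )
}

ensure_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
}

# Walk a CIGAR string; returns per-op tibble with op, len, and the 0-based
# reference/query offsets at which each op starts.
cigar_walk <- function(cigar, ref_start) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  consumes_q <- ops %in% c("M", "I", "S", "=", "X")
  consumes_r <- ops %in% c("M", "D", "N", "=", "X")
  qoff <- cumsum(c(0L, ifelse(consumes_q, lens, 0L)))[seq_along(ops)]
  roff <- ref_start + cumsum(c(0L, ifelse(consumes_r, lens, 0L)))[seq_along(ops)]
  tibble(op = ops, len = lens, qpos = qoff, rpos = roff)
}
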