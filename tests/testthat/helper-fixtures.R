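# Small in-code fixtures shared across test files.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

tiny_lib <- function() {
  withr::with_seed(42, te_library_tbl(
    name = c("gypsy1", "gypsy2", "jockey1", "pogo1"),
    group = c("LTR", "LTR", "LINE", "DNA"),
    sequence = c(random_seq(400), random_seq(500), random_seq(450),
                 random_seq(300)),
    tsd_size = c(4L, 5L, NA, NA)
  ))
}

# minimal single-contig SAM file; records = list of c(qname, flag, pos1, cigar, seq)
write_tiny_sam <- function(records, contig = "chr1", contig_len = 100000,
                           path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len),
    vapply(records, function(r) {
      paste(r[1], r[2], contig, r[3], "60", r[4], "*", "0", "0", r[5],
            strrep("I", nchar(r[5])), sep = "\t")
    }, "")
  )
  writeLines(lines, path)
  path
}

# an alignment-records row as produced by read_alignment_records()
aln_row <- function(read_id, cigar, seq, ref_start = 0L, contig = "chr1",
                    sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, read_id = read_id, contig = contig,
                 ref_start = as.integer(ref_start), strand = "+",
                 cigar = cigar, seq = seq)
}
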