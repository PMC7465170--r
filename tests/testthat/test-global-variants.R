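test_that("CIGAR insertion and deletion ops become SV records at the right coordinates", {
  withr::with_seed(21, {
    ref <- random_seq(5000)
    ins_seq <- random_seq(1500)
  })
  # assembly = ref with 1500 nt inserted after reference position 2000
  asm <- paste0(substr(ref, 1, 2000), ins_seq, substr(ref, 2001, 5000))
  aln <- aln_row("asm1", "2000M1500I3000M", asm)
  svs <- extract_sv(aln, c(chr1 = ref))
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$kind, "insertion")
  expect_equal(svs$start, 2000L)
  expect_equal(svs$end, 2000L)
  expect_equal(svs$sequence, ins_seq)

  # below the floor: nothing
  small <- aln_row("asm2", "2000M30I2980M",
                   paste0(substr(ref, 1, 2000), strrep("A", 30),
                          substr(ref, 2001, 4980)))
  expect_equal(nrow(extract_sv(small, c(chr1 = ref))), 0L)

  # deletion carries the removed reference slice
  del <- aln_row("asm3", "1000M200D1000M",
                 paste0(substr(ref, 1, 1000), substr(ref, 1201, 2200)))
  sv_del <- extract_sv(del, c(chr1 = ref))
  expect_equal(sv_del$kind, "deletion")
  expect_equal(sv_del$start, 1000L)
  expect_equal(sv_del$end, 1200L)
  expect_equal(sv_del$sequence, substr(ref, 1001, 1200))

  # round trip: re-inserting the sequence at its coordinate rebuilds the assembly
  rebuilt <- paste0(substr(ref, 1, svs$start), svs$sequence,
                    substr(ref, svs$start + 1, 5000))
  expect_equal(rebuilt, asm)
})

test_that("CIGAR beyond the sequence end is an error", {
  aln <- aln_row("bad", "100M500I100M", strrep("A", 300))
  expect_error(extract_sv(aln, c(chr1 = strrep("A", 1000))), "beyond")
})

test_that("SAM records load with 0-based coordinates and sequence", {
  sam <- write_tiny_sam(list(
    c("r1", "0", "101", "50M", strrep("ACGTT", 10)),
    c("r2", "16", "201", "20M10I20M", strrep("GATTC", 10))
  ))
  rec <- read_alignment_records(sam, "sampleX")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$ref_start, c(100L, 200L))
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$cigar[2], "20M10I20M")
  expect_equal(nchar(rec$seq), c(50L, 50L))
  expect_equal(rec$sample_id, rep("sampleX", 2))
})

test_that("classification accepts a verbatim consensus and applies strict thresholds", {
  lib <- tiny_lib()
  sv <- tibble::tibble(sample_id = "s1", read_id = "a", contig = "chr1",
                       start = 10L, end = 10L, kind = "insertion",
                       sequence = lib$sequence[1])
  call <- classify_sv(sv, lib)
  expect_true(call$accepted)
  expect_equal(call$family, "gypsy1")
  expect_equal(call$identity, 100)
  expect_equal(call$consensus_coverage, 1.0)

  # 79% of the consensus at 100% identity: coverage below the strict 0.80
  sv79 <- dplyr::mutate(sv, sequence = substr(lib$sequence[1], 1, 316))
  expect_false(classify_sv(sv79, lib)$accepted)
  expect_true(classify_sv(sv79, lib, min_coverage = 0.70)$accepted)
  # unfiltered wild-type mode: any best hit is accepted
  expect_true(classify_sv(sv79, lib, min_coverage = 0, min_identity = 0)$accepted)
  expect_error(classify_sv(sv, lib[0, ]), "empty")
})

test_that("acceptance is monotone in the thresholds", {
  lib <- tiny_lib()
  withr::with_seed(22, {
    svs <- tibble::tibble(
      sample_id = "s1", read_id = letters[1:4], contig = "chr1",
      start = 1:4, end = 1:4, kind = "insertion",
      sequence = c(lib$sequence[2],
                   substr(lib$sequence[2], 1, 420),
                   substr(lib$sequence[3], 50, 440),
                   random_seq(200))
    )
  })
  strict <- classify_sv(svs, lib, min_coverage = 0.9, min_identity = 90)
  loose <- classify_sv(svs, lib, min_coverage = 0.5, min_identity = 50)
  expect_true(all(loose$accepted[strict$accepted]))
})

test_that("copy_table counts accepted insertions per sample and family", {
  calls <- tibble::tibble(
    sample_id = c("A", "A", "A", "A", "A", "B"),
    kind = c(rep("insertion", 5), "deletion"),
    family = c("roo", "roo", "roo", "pogo", "pogo", "roo"),
    accepted = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  tab <- copy_table(calls)
  expect_equal(tab$n[tab$sample_id == "A" & tab$family == "roo"], 3L)
  expect_equal(tab$n[tab$sample_id == "A" & tab$family == "pogo"], 2L)
  expect_equal(sum(tab$n), sum(calls$accepted & calls$kind == "insertion"))
  calls$accepted[1] <- FALSE
  expect_equal(sum(copy_table(calls)$n), 4L)
})

test_that("shared insertions match by family and proximity, each call once", {
  mk <- function(starts, fams) {
    tibble::tibble(sample_id = "x", contig = "chr1", start = starts,
                   end = starts, kind = "insertion", family = fams,
                   accepted = TRUE)
  }
  a <- mk(c(1000L, 5000L), c("roo", "pogo"))
  expect_equal(shared_insertions(a, a), 2L)
  expect_equal(shared_insertions(mk(1000L, "roo"), mk(1090L, "roo")), 1L)
  expect_equal(shared_insertions(mk(1000L, "roo"), mk(1000L, "pogo")), 0L)
  # greedy one-to-one: two calls in a cannot both claim the single b call
  expect_equal(shared_insertions(mk(c(1000L, 1010L), c("roo", "roo")),
                                 mk(1005L, "roo")), 1L)
})
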