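# Build a read carrying [TSD][TE][TSD] with given flanks, returning the read
# and the span of the TE within it.
junction_read <- function(up, te, down, tsd) {
  read <- paste0(up, tsd, te, tsd, down)
  span <- list(te_start = nchar(up) + nchar(tsd),
               te_end = nchar(up) + nchar(tsd) + nchar(te),
               strand = "+", family = "fam")
  list(read = read, span = span)
}

test_that("the TE span within a read is located on either strand", {
  withr::with_seed(41, {
    cons <- random_seq(300)
    pre <- random_seq(100); post <- random_seq(100)
  })
  read <- paste0(pre, cons, post)
  span <- te_span_in_read(read, cons)
  expect_equal(span$te_start, 100L)
  expect_equal(span$te_end, 400L)
  expect_equal(span$strand, "+")

  span_rc <- te_span_in_read(paste0(pre, revcomp(cons), post), cons)
  expect_equal(span_rc$te_start, 100L)
  expect_equal(span_rc$te_end, 400L)
  expect_equal(span_rc$strand, "-")

  expect_error(te_span_in_read(strrep("AT", 100), strrep("GC", 50)),
               "TE not found")
})

test_that("automatic detection finds a junction duplication within the jitter", {
  withr::with_seed(42, {
    up26 <- random_seq(26); down26 <- random_seq(26)
    te <- random_seq(200)
  })
  # duplication flush at both junctions
  jr <- junction_read(paste0("TTTT", up26), te, paste0(down26, "AAAA"), "GCGC")
  res <- detect_tsd_auto(jr$read, jr$span, k = 4)
  expect_true(res$found)
  expect_equal(res$tsd, "GCGC")
  expect_equal(nchar(res$upstream_flank), 30L)

  # no duplication
  read2 <- paste0(up26, "TTTT", "GCGC", te, "TACG", down26, "AAAA")
  span2 <- list(te_start = 34L, te_end = 234L)
  res2 <- detect_tsd_auto(read2, span2, k = 4)
  expect_false(res2$found)

  # duplication offset 2 nt into the downstream flank, still within jitter;
  # a homopolymer upstream flank avoids accidental competing duplications
  read3 <- paste0(strrep("A", 26), "GCGC", te, "AT", "GCGC",
                  substr(down26, 1, 24))
  span3 <- list(te_start = 30L, te_end = 230L)
  res3 <- detect_tsd_auto(read3, span3, k = 4)
  expect_true(res3$found)
  expect_equal(res3$tsd, "GCGC")

  # flanks shorter than requested are an error
  expect_error(detect_tsd_auto(substr(jr$read, 20, 300),
                               list(te_start = 15L, te_end = 215L), 4),
               "insufficient flank")
})

test_that("empty-site correction rescues junctions broken by single read errors", {
  withr::with_seed(43, {
    genome <- random_seq(400)
    te <- random_seq(250)
  })
  site <- 200L
  tsd <- substr(genome, site + 1, site + 4)
  # the inserted allele: genome up to site+4, TE, then genome from site+1 on
  up_g <- substr(genome, site - 25, site + 4)      # 30 nt ending with the target
  down_g <- substr(genome, site + 1, site + 30)    # 30 nt starting with it
  clean <- paste0(substr(genome, 1, site + 4), te,
                  substr(genome, site + 1, 400))
  span <- list(te_start = site + 4L, te_end = site + 4L + 250L)

  clean_res <- detect_tsd_corrected(clean, span, genome, site, 4)
  expect_true(clean_res$found)
  expect_equal(clean_res$tsd, tsd)

  # substitute one base inside the downstream copy of the TSD
  broken <- clean
  mut_pos <- site + 4 + 250 + 2  # third base of the downstream TSD copy
  old <- substr(broken, mut_pos, mut_pos)
  substr(broken, mut_pos, mut_pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  expect_false(detect_tsd_auto(broken, span, 4)$found)
  fixed <- detect_tsd_corrected(broken, span, genome, site, 4)
  expect_true(fixed$found)
  expect_equal(fixed$tsd, tsd)
  expect_equal(fixed$mode, "corrected")
  expect_equal(nchar(fixed$tsm), 6L)

  # delete one base inside the upstream copy
  del <- paste0(substr(clean, 1, site + 1), substr(clean, site + 3, nchar(clean)))
  span_del <- list(te_start = site + 3L, te_end = site + 3L + 250L)
  expect_false(detect_tsd_auto(del, span_del, 4)$found)
  expect_true(detect_tsd_corrected(del, span_del, genome, site, 4)$found)

  # flanks unrelated to the empty site must not be "corrected" into a TSD
  withr::with_seed(44, rnd <- paste0(random_seq(60), te, random_seq(60)))
  span_rnd <- list(te_start = 60L, te_end = 310L)
  expect_false(detect_tsd_corrected(rnd, span_rnd, genome, site, 4)$found)
})

test_that("correction preserves any junction the automatic mode already resolves", {
  withr::with_seed(45, {
    genome <- random_seq(400)
    te <- random_seq(250)
  })
  site <- 150L
  clean <- paste0(substr(genome, 1, site + 4), te,
                  substr(genome, site + 1, 400))
  span <- list(te_start = site + 4L, te_end = site + 4L + 250L)
  auto <- detect_tsd_auto(clean, span, 4)
  corr <- detect_tsd_corrected(clean, span, genome, site, 4)
  expect_true(auto$found)
  expect_true(corr$found)
  expect_equal(corr$tsd, auto$tsd)
})

test_that("the target site motif is the TSD plus one genomic nt on each side", {
  empty <- "TTTAGCGCATTT"
  expect_equal(extract_tsm(empty, 4, 4), "AGCGCA")
  expect_equal(nchar(extract_tsm(empty, 4, 5)), 7L)
  # a reverse-palindromic target site yields a motif equal to its own
  # reverse complement
  tsm <- extract_tsm("TTTAGCGCTTTT", 4, 4)
  expect_equal(tsm, "AGCGCT")
  expect_equal(tsm, revcomp(tsm))
  expect_error(extract_tsm("GCGCAA", 0, 4), "edge")
})

test_that("position frequency matrices count bases and score information", {
  one <- build_pfm("ACGT")
  expect_equal(unname(colSums(unclass(one))), rep(1L, 4))
  expect_equal(information_content(one), rep(2, 4))

  two <- build_pfm(c("AAAA", "CCCC"))
  expect_equal(unname(colSums(unclass(two))), rep(2L, 4))
  expect_equal(information_content(two), rep(1, 4))

  expect_error(build_pfm(character(0)), "no sequences")
  expect_error(build_pfm(c("ACGT", "ACG")), "same length")

  withr::with_seed(46, seqs <- replicate(20, random_seq(6)))
  pfm <- build_pfm(seqs)
  expect_equal(unname(colSums(unclass(pfm))), rep(20L, 6))
  ic <- information_content(pfm)
  expect_true(all(ic >= 0 & ic <= 2))
})
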