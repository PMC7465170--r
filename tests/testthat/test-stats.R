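test_that("transition/transversion fractions classify columns by purine class", {
  expect_equal(pairwise_PQ("AAAA", "AAAA"), c(P = 0, Q = 0))
  expect_equal(pairwise_PQ("AAAA", "GAAA"), c(P = 0.25, Q = 0))
  # A/C and A/T columns are transversions; the A/A columns match
  expect_equal(pairwise_PQ("AAAA", "CATA"), c(P = 0, Q = 0.5))
  # gap and N columns drop out of the denominator
  expect_equal(pairwise_PQ("A-GN", "AAGA"), c(P = 0, Q = 0))
  expect_equal(pairwise_PQ("AG--", "GGTT"), c(P = 0.5, Q = 0))
  expect_error(pairwise_PQ("----", "AAAA"), "no comparable")
  expect_error(pairwise_PQ("AA", "AAA"), "equal length")
})

test_that("the K2P closed form evaluates and saturates as expected", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(round(k2p_distance(0.1, 0.05), 4), 0.1702)
  expect_error(k2p_distance(0.5, 0), "undefined")
  expect_error(k2p_distance(0, 0.5), "undefined")
  # Jensen-type bound and monotonicity in P
  withr::with_seed(61, {
    for (rep in 1:20) {
      P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.2)
      if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0) {
        d <- k2p_distance(P, Q)
        expect_gte(d + 1e-12, P + Q)
        expect_gt(k2p_distance(P + 0.01, Q), d)
      }
    }
  })
})

test_that("family divergence averages per-copy distances and flags saturation", {
  same <- tibble::tibble(copy = c("ACGTACGT", "ACGTACGT"),
                         consensus = c("ACGTACGT", "ACGTACGT"))
  fd0 <- family_divergence(same)
  expect_equal(fd0$mean_d, 0)
  expect_equal(fd0$n_used, 2L)

  withr::with_seed(62, cons <- random_seq(500))
  mutate_ts <- function(s, n) {
    # transitions only, at n random positions
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), n)
    ch[pos] <- ts[ch[pos]]
    paste(ch, collapse = "")
  }
  withr::with_seed(63, pairs <- tibble::tibble(
    copy = c(mutate_ts(cons, 20), mutate_ts(cons, 50)),
    consensus = cons
  ))
  fd <- family_divergence(pairs)
  expect_equal(fd$mean_d, mean(fd$per_copy$d))
  expect_equal(fd$per_copy$P, c(20, 50) / 500)
  # mean of the two per-copy distances, as for any arithmetic average
  expect_equal(fd$mean_d,
               (k2p_distance(0.04, 0) + k2p_distance(0.1, 0)) / 2)

  sat <- tibble::tibble(copy = strrep("A", 10), consensus = strrep("G", 10))
  expect_error(family_divergence(sat), "saturated")
})

test_that("binomial upper tails are exact", {
  expect_equal(binom_tail(10, 0.5, 0), 1)
  expect_equal(binom_tail(10, 0.5, 9), 11 / 1024)
  expect_equal(binom_tail(10, 0, 1), 0)
  expect_equal(binom_tail(10, 1, 10), 1)
  expect_error(binom_tail(10, 0.5, 11), "out-of-range")
  expect_error(binom_tail(10, 1.5, 2), "out-of-range")
  withr::with_seed(64, {
    for (rep in 1:20) {
      n <- sample(1:12, 1); p <- runif(1); k <- sample(0:n, 1)
      expect_equal(binom_tail(n, p, k), oracle_binom_tail(n, p, k),
                   tolerance = 1e-12)
    }
  })
})

test_that("the minimal significant count brackets the alpha threshold", {
  expect_equal(min_significant(10, 0.5), 9)
  expect_lt(binom_tail(10, 0.5, 9), 0.05)
  expect_gte(binom_tail(10, 0.5, 8), 0.05)
  expect_equal(min_significant(1, 0.9), 2)  # unreachable: n + 1
  # non-increasing in alpha
  expect_gte(min_significant(50, 0.1, 0.01), min_significant(50, 0.1, 0.10))
})

test_that("the trap test measures the merged cluster fraction and in-cluster count", {
  pos <- tibble::tibble(contig = "chr1", position = c(100L, 5000L, 9000L))
  none <- trap_test(pos, tibble::tibble(contig = character(),
                                        start = integer(), end = integer()),
                    genome_length = 10000)
  expect_equal(none$p, 0)
  expect_equal(none$k, 0L)
  expect_equal(none$pvalue, 1)

  all_cov <- trap_test(pos, tibble::tibble(contig = "chr1", start = 0L,
                                           end = 10000L),
                       genome_length = 10000)
  expect_equal(all_cov$p, 1)
  expect_equal(all_cov$k, 3L)
  expect_equal(all_cov$pvalue, 1)

  # half-open membership: a position at the interval end is outside
  edge <- trap_test(tibble::tibble(contig = "chr1", position = c(200L, 199L)),
                    tibble::tibble(contig = "chr1", start = 100L, end = 200L),
                    genome_length = 1000)
  expect_equal(edge$k, 1L)
  expect_error(trap_test(pos, tibble::tibble(contig = "chr1", start = 0L,
                                             end = 100L), genome_length = 0),
               "positive")
})

test_that("overlapping clusters merge before the genome fraction is computed", {
  withr::with_seed(65, {
    for (rep in 1:15) {
      n_int <- sample(1:8, 1)
      s <- sample(0:9000, n_int, replace = TRUE)
      cl <- tibble::tibble(contig = "chr1", start = s,
                           end = s + sample(50:2000, n_int, replace = TRUE))
      cl$end <- pmin(cl$end, 10000L)
      tt <- trap_test(tibble::tibble(contig = "chr1", position = 1L), cl,
                      genome_length = 10000)
      expect_equal(tt$p, oracle_interval_fraction(cl, 10000))
    }
  })
})

test_that("trap test tidiers expose the test quantities", {
  tt <- trap_test(tibble::tibble(contig = "chr1", position = c(10L, 900L)),
                  tibble::tibble(contig = "chr1", start = 0L, end = 100L),
                  genome_length = 1000)
  td <- tidy(tt)
  expect_equal(td$n, 2L)
  expect_equal(td$k, 1L)
  expect_equal(td$p, 0.1)
  expect_equal(td$pvalue, binom_tail(2, 0.1, 1))
  expect_s3_class(glance(tt), "tbl_df")
})
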