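test_that("random genomes are reproducible with the stated composition", {
  g1 <- random_genome(10000, seed = 1)
  g2 <- random_genome(10000, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 10000L)
  expect_false(identical(g1, random_genome(10000, seed = 2)))

  gc_only <- random_genome(500, gc = 1, seed = 3)
  expect_true(grepl("^[GC]+$", gc_only))

  # empirical GC within 3 binomial standard errors of the target
  big <- random_genome(100000, gc = 0.42, seed = 4)
  gc_obs <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  se <- sqrt(0.42 * 0.58 / 100000)
  expect_lt(abs(gc_obs - 0.42), 3 * se)
  expect_error(random_genome(100, gc = 1.5), "gc")
})

test_that("implantation duplicates the target and accounts for every base", {
  lib <- tiny_lib()
  withr::with_seed(81, genome <- random_seq(10000))
  sim <- implant_insertions(genome, lib,
                            tibble::tibble(position = 4000L, family = "gypsy1",
                                           class = "fixed", frequency = NA))
  te_len <- nchar(lib$sequence[lib$name == "gypsy1"])
  expect_equal(nchar(sim$assembly), 10000L + te_len + 4L)
  expect_equal(sim$truth$tsd, substr(genome, 4001, 4004))
  # locus structure: [target][TE][target]
  expect_equal(substr(sim$assembly, 4001, 4004), sim$truth$tsd)
  expect_equal(substr(sim$assembly, 4005, 4004 + te_len),
               lib$sequence[lib$name == "gypsy1"])
  expect_equal(substr(sim$assembly, 4005 + te_len, 4008 + te_len),
               sim$truth$tsd)

  none <- implant_insertions(genome, lib, tibble::tibble(position = integer(),
                                                         family = character(),
                                                         class = character()))
  expect_identical(none$assembly, genome)
  expect_equal(nrow(none$truth), 0L)

  expect_error(implant_insertions(genome, lib,
                                  tibble::tibble(position = c(100L, 102L),
                                                 family = "gypsy1",
                                                 class = "fixed")),
               "overlapping")
})

test_that("minor insertions stay out of the assembly but enter read templates", {
  lib <- tiny_lib()
  withr::with_seed(82, genome <- random_seq(20000))
  sim <- implant_insertions(genome, lib,
                            tibble::tibble(position = 10000L,
                                           family = "gypsy2",
                                           class = "minor", frequency = 1))
  expect_identical(sim$assembly, genome)
  reads <- long_reads(sim, coverage = 3, mean_len = 4000, seed = 83)
  carriers <- reads[vapply(reads$carries, length, 1L) > 0, ]
  expect_gt(nrow(carriers), 0)
  # a carrier read contains the full TE sequence verbatim (frequency 1)
  te <- lib$sequence[lib$name == "gypsy2"]
  spanning <- carriers[carriers$start < 10000 - 10 &
                       carriers$start + carriers$length > 10000 + nchar(te) + 10, ]
  if (nrow(spanning) > 0) {
    oriented <- ifelse(spanning$strand == "-", revcomp(spanning$seq),
                       spanning$seq)
    expect_true(all(vapply(oriented, function(s) grepl(te, s, fixed = TRUE),
                           TRUE)))
  }
})

test_that("error-free long reads are exact substrings and coverage is honoured", {
  lib <- tiny_lib()
  withr::with_seed(84, genome <- random_seq(50000))
  sim <- implant_insertions(genome, lib, tibble::tibble(position = integer(),
                                                        family = character(),
                                                        class = character()))
  reads <- long_reads(sim, coverage = 30, mean_len = 5000, seed = 85)
  total <- sum(nchar(reads$seq))
  expect_lt(abs(total - 30 * 50000) / (30 * 50000), 0.10)
  oriented <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
  expect_identical(unname(oriented[1:10]),
                   substring(genome, reads$start[1:10] + 1,
                             reads$start[1:10] + reads$length[1:10]))

  again <- long_reads(sim, coverage = 30, mean_len = 5000, seed = 85)
  expect_identical(reads, again)

  noisy <- long_reads(sim, coverage = 2, mean_len = 5000,
                      profile = ont_error_profile(0.10), seed = 86)
  expect_false(any(noisy$seq[1:5] == ifelse(noisy$strand[1:5] == "-",
                                            revcomp(substring(genome,
                                                              noisy$start[1:5] + 1,
                                                              noisy$start[1:5] + noisy$length[1:5])),
                                            substring(genome, noisy$start[1:5] + 1,
                                                      noisy$start[1:5] + noisy$length[1:5]))))
})

test_that("paired-read truth reflects the insertion content of the template", {
  lib <- tiny_lib()
  withr::with_seed(87, genome <- random_seq(10000))
  empty <- implant_insertions(genome, lib,
                              tibble::tibble(position = integer(),
                                             family = character(),
                                             class = character()))
  p0 <- paired_reads(empty, 500, seed = 88)
  expect_equal(sum(p0$truth_discordant), 0L)
  expect_identical(p0, paired_reads(empty, 500, seed = 88))

  one <- implant_insertions(genome, lib,
                            tibble::tibble(position = 5000L, family = "gypsy2",
                                           class = "fixed", frequency = NA))
  two <- implant_insertions(genome, lib,
                            tibble::tibble(position = c(3000L, 7000L),
                                           family = c("gypsy2", "gypsy1"),
                                           class = "fixed", frequency = NA))
  d1 <- sum(paired_reads(one, 3000, seed = 89)$truth_discordant)
  d2 <- sum(paired_reads(two, 3000, seed = 89)$truth_discordant)
  expect_gt(d1, 0)
  expect_gt(d2, d1)  # discordant fraction grows with insertion density
})

test_that("error profiles validate their rates", {
  expect_error(error_profile(substitution = 0.3), "rates")
  expect_error(error_profile(0.2, 0.2, 0.15), "rates")
  p <- ont_error_profile(0.05)
  expect_equal(p$substitution, 0.02)
  expect_equal(p$insertion + p$deletion, 0.03)
})
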