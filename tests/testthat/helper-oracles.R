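# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain dynamic programming tables and exhaustive
# enumeration, usable only at small problem sizes.

# Affine-gap Smith-Waterman best score (Gotoh), one strand.
# A gap of length L costs -(gap_open + gap_extend * L) like the package's
# scoring scheme.
gotoh_local_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  open <- -(gap_open + gap_extend)  # cost of the first gap column
  ext <- -gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# both-strand local score, as searched by local_align()
oracle_local_score <- function(a, b, ...) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(a, "")[[1]]), collapse = ""))
  max(gotoh_local_score(a, b, ...), gotoh_local_score(rc, b, ...))
}

# Levenshtein distance by the full Wagner-Fischer table (row-vectorized)
oracle_edit_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- 0:length(bv)
  for (i in seq_along(av)) {
    cur <- numeric(length(bv) + 1)
    cur[1] <- i
    for (j in seq_along(bv)) {
      cur[j + 1] <- min(prev[j] + (av[i] != bv[j]), prev[j + 1] + 1,
                        cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(bv) + 1]
}

# transitive-closure clustering oracle: positions i, j are linked when
# |p_i - p_j| <= max_gap; clusters are the connected components
oracle_cluster_components <- function(positions, max_gap) {
  n <- length(positions)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(positions[i] - positions[j]) <= max_gap &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(split(positions, comp))
}

# upper binomial tail by direct pmf enumeration
oracle_binom_tail <- function(n, p, k) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# merged-interval genome fraction by per-base membership
oracle_interval_fraction <- function(clusters, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_len(nrow(clusters))) {
    s <- clusters$start[i]; e <- clusters$end[i]
    if (e > s) covered[(s + 1):e] <- TRUE
  }
  mean(covered)
}
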