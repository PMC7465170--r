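#' Transition/transversion difference fractions of an aligned pair
#'
#' Compares two gapped sequences column by column, restricted to columns
#' where both characters are in `{A,C,G,T}` (gap and `N` columns are
#' excluded from the denominator). `P` is the fraction of transition
#' differences (A<->G, C<->T), `Q` the fraction of transversions.
#'
#' @param a,b equal-length (gapped) sequence strings.
#' @return named numeric vector `c(P = ..., Q = ...)`.
#' @export
pairwise_PQ <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% BASES & cb %in% BASES
  n <- sum(ok)
  if (n == 0) abort("no comparable columns")
  ca <- ca[ok]; cb <- cb[ok]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- ca != cb
  transition <- diff & (purine[ca] == purine[cb])
  c(P = sum(transition) / n, Q = sum(diff & !transition) / n)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions per site,
#' where `P` and `Q` are the transition and transversion difference
#' fractions. Defined only while `1 - 2P - Q > 0` and `1 - 2Q > 0`
#' (saturation otherwise).
#'
#' @param P,Q transition and transversion fractions.
#' @return the distance in substitutions/site.
#' @export
k2p_distance <- function(P, Q) {
  if (P < 0 || Q < 0 || P + Q > 1) abort("invalid P/Q")
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    abort("distance undefined (saturated)")
  }
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

#' Average intra-family Kimura divergence
#'
#' Mean K2P distance of TE copies against their family consensus. Input is
#' one aligned pair per copy (gapped, equal-length strings); copies with a
#' saturated (undefined) distance are excluded from the mean and counted.
#'
#' @param copies tibble with columns `copy` and `consensus` holding the
#'   gapped aligned sequences, one row per copy. [align_copies()] builds
#'   this from raw sequences.
#' @return a list with `mean_d`, `n_used`, `n_saturated`, and `per_copy`
#'   (tibble of `P`, `Q`, `d`).
#' @export
family_divergence <- function(copies) {
  per <- map(seq_len(nrow(copies)), function(i) {
    pq <- pairwise_PQ(copies$copy[i], copies$consensus[i])
    d <- tryCatch(k2p_distance(pq["P"], pq["Q"]), error = function(e) NA_real_)
    tibble(P = unname(pq["P"]), Q = unname(pq["Q"]), d = d)
  }) %>% bind_rows()
  ok <- !is.na(per$d)
  if (!any(ok)) abort("all copies saturated: no defined distance")
  list(mean_d = mean(per$d[ok]), n_used = sum(ok), n_saturated = sum(!ok),
       per_copy = per)
}

#' Align TE copies to their consensus for divergence estimation
#'
#' Global minimum-edit alignment of each copy against the consensus,
#' returning the gapped pairs consumed by [family_divergence()].
#'
#' @param copy_seqs character vector of copy sequences.
#' @param consensus consensus sequence string.
#' @return tibble with columns `copy`, `consensus`.
#' @export
align_copies <- function(copy_seqs, consensus) {
  rows <- map(copy_seqs, function(s) {
    a <- global_edit_align(s, consensus)
    tibble(copy = a$pattern, consensus = a$subject)
  })
  bind_rows(rows)
}

#' Upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed exactly (no normal
#' approximation).
#'
#' @param n number of trials.
#' @param p success probability.
#' @param k observed count.
#' @return the one-tailed p-value.
#' @export
binom_tail <- function(n, p, k) {
  if (n < 0 || k < 0 || k > n || p < 0 || p > 1) abort("out-of-range arguments")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Minimal count rejecting the binomial null
#'
#' Smallest `k` with `P(X >= k) < alpha` under `Binomial(n, p)` (strict
#' inequality); `n + 1` if no achievable count rejects.
#'
#' @inheritParams binom_tail
#' @param alpha significance level (default 0.05).
#' @return an integer in `0:(n + 1)`.
#' @export
min_significant <- function(n, p, alpha = 0.05) {
  for (k in 0:n) {
    if (binom_tail(n, p, k) < alpha) return(k)
  }
  n + 1L
}

#' Binomial "trap model" test of piRNA-cluster insertion enrichment
#'
#' Under the trap model, TE invasions are stopped by copies landing in
#' piRNA clusters, so new insertions should be enriched there. The null is
#' uniform insertion: each of the `n` insertions falls inside a cluster
#' with probability `p` equal to the merged cluster fraction of the genome.
#' The observed in-cluster count `k` is assessed with a one-tailed exact
#' binomial test.
#'
#' @param positions tibble of insertion positions with columns `contig`,
#'   `position` (0-based), e.g. accepted MIV calls.
#' @param clusters tibble of cluster intervals with columns `contig`,
#'   `start`, `end` (0-based half-open); overlapping intervals are merged
#'   before computing `p`.
#' @param genome_length total assembly length in nt.
#' @param alpha significance level (default 0.05).
#' @return a `trap_test` object with fields `n`, `p`, `k`, `pvalue`,
#'   `min_significant`, `alpha`; see also [tidy()] and [glance()] methods.
#' @export
trap_test <- function(positions, clusters, genome_length, alpha = 0.05) {
  if (genome_length <= 0) abort("genome_length must be positive")
  n <- nrow(positions)
  if (nrow(clusters)) {
    by_contig <- split(clusters, clusters$contig)
    merged <- imap(by_contig, function(d, ctg) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      tibble(contig = ctg, start = IRanges::start(r) - 1L,
             end = IRanges::end(r))
    }) %>% bind_rows()
  } else {
    merged <- tibble(contig = character(), start = integer(), end = integer())
  }
  total <- sum(merged$end - merged$start)
  if (total > genome_length) abort("clusters exceed genome_length after merging")
  p <- total / genome_length
  k <- 0L
  if (n > 0 && nrow(merged)) {
    k <- sum(map_int(seq_len(n), function(i) {
      m <- merged[merged$contig == positions$contig[i], ]
      as.integer(any(positions$position[i] >= m$start &
                     positions$position[i] < m$end))
    }))
  }
  structure(
    list(n = n, p = p, k = k,
         pvalue = if (n > 0) binom_tail(n, p, k) else 1,
         min_significant = if (n > 0) min_significant(n, p, alpha) else 1L,
         alpha = alpha, cluster_fraction = p, genome_length = genome_length,
         n_clusters = nrow(merged)),
    class = "trap_test"
  )
}

#' @export
print.trap_test <- function(x, ...) {
  cat(sprintf(
    paste0("Binomial trap-model test\n",
           "  insertions (n):        %d\n",
           "  cluster fraction (p):  %.4f\n",
           "  in-cluster count (k):  %d (%.2f%%)\n",
           "  one-tailed p-value:    %.4g\n",
           "  minimal significant k: %d (alpha = %g)\n"),
    x$n, x$p, x$k, if (x$n > 0) 100 * x$k / x$n else 0,
    x$pvalue, x$min_significant, x$alpha))
  invisible(x)
}

#' @export
#' @method tidy trap_test
tidy.trap_test <- function(x, ...) {
  tibble(n = x$n, p = x$p, k = x$k, pvalue = x$pvalue,
         min_significant = x$min_significant, alpha = x$alpha)
}

#' @export
#' @method glance trap_test
glance.trap_test <- function(x, ...) {
  tibble(pvalue = x$pvalue, significant = x$pvalue < x$alpha,
         min_significant = x$min_significant)
}
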