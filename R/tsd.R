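#' Locate the TE span within a single read
#'
#' Best local alignment of a family consensus against the read (both
#' strands); the covered read interval delimits the putative insertion, and
#' its flanks carry the integration junctions.
#'
#' @param read_seq the read sequence.
#' @param consensus a one-row `te_library` tibble, or a consensus sequence
#'   string.
#' @param scoring an [align_scoring()] scheme.
#' @return a list with `te_start`, `te_end` (0-based half-open read
#'   coordinates), `strand`, and `family`.
#' @export
te_span_in_read <- function(read_seq, consensus, scoring = align_scoring()) {
  if (is.data.frame(consensus)) {
    fam <- consensus$name[1]; cons <- consensus$sequence[1]
  } else {
    fam <- NA_character_; cons <- consensus
  }
  aln <- local_align(cons, read_seq, scoring)
  if (is.null(aln)) abort("TE not found in read")
  list(te_start = aln$target_interval[1], te_end = aln$target_interval[2],
       strand = aln$strand, family = fam)
}

tsd_result <- function(mode, found, tsd = "", size = NA_integer_, tsm = "",
                       upstream_flank = "", downstream_flank = "") {
  tibble(mode = mode, found = found, tsd = tsd,
         size = as.integer(size), tsm = tsm,
         upstream_flank = upstream_flank, downstream_flank = downstream_flank)
}

read_flanks <- function(read_seq, span, flank) {
  if (span$te_start < flank || nchar(read_seq) - span$te_end < flank) {
    abort("insufficient flank")
  }
  list(up = substr0(read_seq, span$te_start - flank, span$te_start),
       down = substr0(read_seq, span$te_end, span$te_end + flank))
}

# k-mer duplication search on a pair of flanks. e = upstream end offset from
# the junction, d = downstream start offset; both must be < jitter. Preference:
# minimal e + d, then minimal max(e, d), then minimal e.
find_duplication <- function(up, down, k, jitter) {
  flank <- nchar(up)
  best <- NULL
  for (e in 0:(jitter - 1L)) {
    if (flank - e - k < 0) break
    up_k <- substr0(up, flank - e - k, flank - e)
    for (d in 0:(jitter - 1L)) {
      if (d + k > nchar(down)) break
      if (up_k == substr0(down, d, d + k)) {
        key <- c(e + d, max(e, d), e)
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(tsd = up_k, e = e, d = d, key = key)
        }
      }
    }
  }
  best
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Automatic TSD detection at an insertion junction within a read
#'
#' Extracts `flank` nt immediately upstream of the TE start and downstream
#' of the TE end, and reports a target site duplication when some `k`-mer
#' ending within the last `jitter` positions of the upstream flank is
#' identical to a `k`-mer starting within the first `jitter` positions of
#' the downstream flank. The junction-proximal match is preferred. Exact
#' `k`-mer equality (rather than fuzzy matching) controls false positives on
#' such short motifs; the jitter absorbs breakpoint imprecision from the
#' local alignment.
#'
#' @param read_seq the read sequence.
#' @param span list from [te_span_in_read()].
#' @param k expected TSD size in nt.
#' @param flank flank length in nt (default 30).
#' @param jitter junction offset tolerance in nt (default 5).
#' @return a one-row tibble (`mode`, `found`, `tsd`, `size`, `tsm`,
#'   `upstream_flank`, `downstream_flank`).
#' @export
detect_tsd_auto <- function(read_seq, span, k, flank = 30, jitter = 5) {
  fl <- read_flanks(read_seq, span, flank)
  hit <- find_duplication(fl$up, fl$down, k, jitter)
  if (is.null(hit)) {
    tsd_result("auto", FALSE, size = k,
               upstream_flank = fl$up, downstream_flank = fl$down)
  } else {
    tsd_result("auto", TRUE, tsd = hit$tsd, size = k,
               upstream_flank = fl$up, downstream_flank = fl$down)
  }
}

# count read-vs-genomic edits within subject (genomic) positions [lo, hi)
# of a global alignment
edits_in_region <- function(aln, lo, hi) {
  p <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  spos <- 0L
  edits <- 0L
  for (i in seq_along(p)) {
    if (s[i] == "-") {                      # insertion in read
      if (spos > lo && spos < hi) edits <- edits + 1L
    } else {
      if (spos >= lo && spos < hi && p[i] != s[i]) edits <- edits + 1L
      spos <- spos + 1L
    }
  }
  edits
}

#' Empty-site guided, error-corrected TSD detection
#'
#' Single long reads carry enough sequencing error that a genuine TSD often
#' fails exact detection. When the assembled genome retains the empty
#' (uninserted) allele of the target site, each read flank can be globally
#' aligned to the corresponding empty-site flank and read errors replaced by
#' genomic bases before re-running the automatic search.
#'
#' The correction never manufactures a TSD from genomic sequence alone:
#' a corrected TSD is reported only if (i) each read flank aligns to its
#' genomic counterpart within `max_flank_dist` edits, and (ii) the read
#' bases aligned to the target `k`-mer on each side differ from it by at
#' most `max_tsd_edits` (the strictness knob), so both junction-defining
#' copies remain supported by the read. If the automatic search already
#' succeeds on the raw flanks, its result is returned unchanged.
#'
#' @param read_seq the read sequence.
#' @param span list from [te_span_in_read()].
#' @param empty_site_seq assembled-genome sequence around the insertion
#'   point (covering at least `flank` nt on each side of the site).
#' @param site 0-based start of the target `k`-mer within `empty_site_seq`.
#' @param k expected TSD size in nt.
#' @param flank,jitter as in [detect_tsd_auto()].
#' @param site_search the true insertion point is searched within
#'   `site_search` nt of `site` (minimum total flank edit distance), to
#'   absorb breakpoint jitter in noisy read alignments (default 5).
#' @param max_flank_dist maximum edits between a read flank and its genomic
#'   counterpart (default `ceiling(flank / 3)`).
#' @param max_tsd_edits maximum residual edits within each read-side copy of
#'   the target `k`-mer (default 1).
#' @return a one-row tibble as in [detect_tsd_auto()], with
#'   `mode = "corrected"`; on success `tsd` is the duplicated genomic
#'   `k`-mer and `tsm` its 1-nt-extended target site motif.
#' @export
detect_tsd_corrected <- function(read_seq, span, empty_site_seq, site, k,
                                 flank = 30, jitter = 5, site_search = 5,
                                 max_flank_dist = NULL, max_tsd_edits = 1) {
  if (is.null(max_flank_dist)) max_flank_dist <- ceiling(flank / 3)
  empty_site_seq <- check_seq(empty_site_seq, "empty_site_seq")
  fl <- read_flanks(read_seq, span, flank)

  auto <- detect_tsd_auto(read_seq, span, k, flank, jitter)
  if (auto$found) {
    auto$mode <- "corrected"
    return(auto)
  }

  sites <- site + seq(-site_search, site_search)
  sites <- sites[sites + k - flank >= 0 & sites + flank <= nchar(empty_site_seq) &
                 sites >= 0]
  if (!length(sites)) abort("empty_site_seq too short")

  best <- NULL
  for (s in sites) {
    g_up <- substr0(empty_site_seq, s + k - flank, s + k)
    g_down <- substr0(empty_site_seq, s, s + flank)
    a_up <- global_edit_align(fl$up, g_up)
    a_down <- global_edit_align(fl$down, g_down)
    tot <- a_up$edit_distance + a_down$edit_distance
    key <- c(tot, abs(s - site), s)
    if (is.null(best) || lex_less(key, best$key)) {
      best <- list(s = s, g_up = g_up, g_down = g_down,
                   a_up = a_up, a_down = a_down, key = key)
    }
  }

  fail <- tsd_result("corrected", FALSE, size = k,
                     upstream_flank = fl$up, downstream_flank = fl$down)
  if (best$a_up$edit_distance > max_flank_dist ||
      best$a_down$edit_distance > max_flank_dist) {
    return(fail)
  }
  # junction support: read bases over each copy of the target k-mer
  if (edits_in_region(best$a_up, flank - k, flank) > max_tsd_edits ||
      edits_in_region(best$a_down, 0, k) > max_tsd_edits) {
    return(fail)
  }
  corr <- find_duplication(best$g_up, best$g_down, k, jitter)
  if (is.null(corr)) return(fail)
  tsm <- tryCatch(extract_tsm(empty_site_seq, best$s, k),
                  error = function(e) "")
  tsd_result("corrected", TRUE, tsd = corr$tsd, size = k, tsm = tsm,
             upstream_flank = best$g_up, downstream_flank = best$g_down)
}

#' Target site motif around a TSD
#'
#' The `(k + 2)`-nt genomic window centred on the `k`-nt target site: the
#' TSD extended by exactly one genomic nt on each side. For a 4-nt TSD this
#' yields the 6-nt target site motif.
#'
#' @param empty_site_seq genomic sequence containing the target site.
#' @param tsd_site 0-based start of the `k`-nt target site within
#'   `empty_site_seq`.
#' @param k TSD size in nt.
#' @return a `(k + 2)`-nt string.
#' @export
extract_tsm <- function(empty_site_seq, tsd_site, k) {
  if (tsd_site < 1 || tsd_site + k + 1 > nchar(empty_site_seq)) {
    abort("target site at sequence edge: no 1-nt context on both sides")
  }
  substr0(empty_site_seq, tsd_site - 1, tsd_site + k + 1)
}

#' Position frequency matrix over equal-length sequences
#'
#' @param seqs character vector of equal-length sequences over `{A,C,G,T}`.
#' @return a `pfm` object: a 4-row (`A`,`C`,`G`,`T`) integer count matrix
#'   with attribute `n_sequences`; every column sums to the sequence count.
#' @export
build_pfm <- function(seqs) {
  if (!length(seqs)) abort("no sequences")
  seqs <- vapply(seqs, check_seq, "", what = "logo sequence", allow_n = FALSE,
                 USE.NAMES = FALSE)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) abort("sequences must all have the same length")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = BASES))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- BASES
  structure(counts, n_sequences = length(seqs), class = c("pfm", "matrix"))
}

#' Per-position information content of a PFM, in bits
#'
#' `2 + sum(f * log2(f))` per column (with `0 * log(0) = 0`); ranges from 0
#' (uniform) to 2 bits (invariant position). This is the column height used
#' by standard sequence logos.
#'
#' @param pfm a [build_pfm()] result.
#' @return numeric vector, one value per position.
#' @export
information_content <- function(pfm) {
  n <- attr(pfm, "n_sequences")
  apply(unclass(pfm), 2, function(col) {
    f <- col / n
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' @export
#' @method tidy pfm
tidy.pfm <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n_sequences") <- NULL
  as_tibble(as.table(m), .name_repair = "minimal") %>%
    rlang::set_names(c("base", "position", "count")) %>%
    mutate(position = as.integer(.data$position))
}
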