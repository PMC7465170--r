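#' Locate a piRNA cluster in an assembly via its flanking sequences
#'
#' Each flank (typically a flanking gene sequence from a prior annotation)
#' is placed in the assembly by best local alignment over all contigs and
#' both strands. With two flanks found on the same contig, the cluster
#' spans from the inner end of the first hit to the inner start of the
#' second (orientation-agnostic: roles swap if the second hit precedes the
#' first). With a single flank, the interval extends `fallback_length` nt
#' downstream of the flank's inner end.
#'
#' @param assembly named character vector or `DNAStringSet` of contigs.
#' @param flank_a,flank_b flanking sequences; `flank_b` may be `NULL`.
#' @param fallback_length cluster length in nt, required when `flank_b` is
#'   `NULL`.
#' @param name cluster name.
#' @param scoring an [align_scoring()] scheme.
#' @return one-row tibble: `name`, `contig`, `start`, `end` (0-based
#'   half-open), `localization_mode`.
#' @export
locate_cluster <- function(assembly, flank_a, flank_b = NULL,
                           fallback_length = NULL, name = "cluster",
                           scoring = align_scoring()) {
  assembly <- as_chr_seqs(assembly)
  hit_of <- function(fl) {
    best <- NULL
    for (ctg in names(assembly)) {
      aln <- local_align(fl, assembly[[ctg]], scoring)
      if (!is.null(aln) && (is.null(best) || aln$score > best$aln$score)) {
        best <- list(contig = ctg, aln = aln)
      }
    }
    best
  }
  ha <- hit_of(flank_a)
  hb <- if (!is.null(flank_b)) hit_of(flank_b) else NULL
  if (is.null(ha) && is.null(hb)) abort("neither flank found in the assembly")
  if (is.null(flank_b)) {
    if (is.null(ha)) abort("neither flank found in the assembly")
    if (is.null(fallback_length)) {
      abort("fallback_length required when only one flank is given")
    }
    s <- ha$aln$target_interval[2]
    return(tibble(name = name, contig = ha$contig, start = s,
                  end = s + as.integer(fallback_length),
                  localization_mode = "one_flank_plus_length"))
  }
  if (is.null(ha) || is.null(hb)) abort("a flank was not found in the assembly")
  if (ha$contig != hb$contig) {
    abort(sprintf("flanks map to different contigs (%s at %s:[%d,%d), %s at %s:[%d,%d))",
                  "flank_a", ha$contig, ha$aln$target_interval[1],
                  ha$aln$target_interval[2],
                  "flank_b", hb$contig, hb$aln$target_interval[1],
                  hb$aln$target_interval[2]))
  }
  # orientation-agnostic: the upstream hit contributes its inner end
  if (ha$aln$target_interval[1] <= hb$aln$target_interval[1]) {
    s <- ha$aln$target_interval[2]; e <- hb$aln$target_interval[1]
  } else {
    s <- hb$aln$target_interval[2]; e <- ha$aln$target_interval[1]
  }
  tibble(name = name, contig = ha$contig, start = s, end = e,
         localization_mode = "two_flanks")
}

#' Filter putative piRNA reads
#'
#' Keeps reads strictly longer than `min_len_exclusive` nt that do not map
#' (end-to-end, either strand, at most `max_mismatches` mismatches) to any
#' known other small-RNA sequence (e.g. miRNA, rRNA fragments).
#'
#' @param reads character vector of small-RNA read sequences.
#' @param exclusion_sets character vector (or `DNAStringSet`) of other
#'   known small-RNA sequences.
#' @param min_len_exclusive length threshold, strict (default 23).
#' @param max_mismatches mismatch tolerance for exclusion matching
#'   (default 2).
#' @return the retained reads (character vector).
#' @export
filter_pirna_reads <- function(reads, exclusion_sets,
                               min_len_exclusive = 23, max_mismatches = 2) {
  reads <- reads[nchar(reads) > min_len_exclusive]
  if (!length(reads) || !length(exclusion_sets)) return(reads)
  if (inherits(exclusion_sets, "DNAStringSet")) {
    exclusion_sets <- as.character(exclusion_sets)
  }
  excl <- Biostrings::DNAStringSet(exclusion_sets)
  hits <- vapply(reads, function(r) {
    n_genome_hits(r, excl, max_mismatches) > 0
  }, logical(1), USE.NAMES = FALSE)
  reads[!hits]
}

n_genome_hits <- function(read, subjects, max_mismatches) {
  tot <- 0L
  for (strand_seq in c(read, revcomp(read))) {
    pat <- Biostrings::DNAString(strand_seq)
    for (i in seq_along(subjects)) {
      tot <- tot + Biostrings::countPattern(pat, subjects[[i]],
                                            max.mismatch = max_mismatches)
    }
  }
  tot
}

#' Positions of uniquely mapping small-RNA reads
#'
#' A read contributes one position iff, among all its alignments with at
#' most `max_mismatches` mismatches (both strands, no indels), exactly one
#' belongs to the best stratum (fewest mismatches) — the behaviour of a
#' best-stratum unique-mapping short-read aligner.
#'
#' @param reads named character vector of read sequences (names become
#'   `read_id`; unnamed reads are numbered).
#' @param assembly named character vector or `DNAStringSet` of contigs.
#' @param max_mismatches mismatch tolerance (default 2).
#' @return tibble: `read_id`, `contig`, `position` (0-based start on the
#'   forward strand), `strand`, `mismatches`.
#' @export
unique_map_counts <- function(reads, assembly, max_mismatches = 2) {
  assembly <- as_chr_seqs(assembly)
  subjects <- Biostrings::DNAStringSet(assembly)
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  rows <- imap(reads, function(r, id) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- Biostrings::DNAString(if (strand == "+") r else revcomp(r))
      for (ctg in names(assembly)) {
        m <- Biostrings::matchPattern(pat, subjects[[ctg]],
                                      max.mismatch = max_mismatches)
        if (length(m)) {
          mm <- vapply(seq_along(m), function(j) {
            sum(strsplit(as.character(m[[j]]), "")[[1]] !=
                strsplit(as.character(pat), "")[[1]])
          }, integer(1))
          hits[[length(hits) + 1L]] <- tibble(
            read_id = id, contig = ctg,
            position = Biostrings::start(m) - 1L,
            strand = strand, mismatches = mm)
        }
      }
    }
    hits <- bind_rows(hits)
    if (!nrow(hits)) return(NULL)
    best <- min(hits$mismatches)
    stratum <- hits[hits$mismatches == best, ]
    if (nrow(stratum) != 1L) return(NULL)
    stratum
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(read_id = character(), contig = character(),
                  position = integer(), strand = character(),
                  mismatches = integer())
  }
  out
}

#' piRNA abundance in fixed genome windows
#'
#' Counts mapped positions per non-overlapping, genome-anchored window
#' (window starts at multiples of `window`), scaled by `normalizer`.
#'
#' @param positions tibble with columns `contig`, `position` (0-based).
#' @param window window size in nt (default 1000).
#' @param normalizer scale factor applied to every count (default 1), e.g.
#'   from [normalize_by_mirna()].
#' @return tibble: `contig`, `window_start`, `count`.
#' @export
window_counts <- function(positions, window = 1000, normalizer = 1) {
  if (window <= 0) abort("window must be positive")
  if (!nrow(positions)) {
    return(tibble(contig = character(), window_start = integer(),
                  count = numeric()))
  }
  positions %>%
    mutate(window_start = (.data$position %/% window) * window) %>%
    count(.data$contig, .data$window_start) %>%
    mutate(count = .data$n * normalizer) %>%
    select("contig", "window_start", "count")
}

#' Retain piRNA-producing regions
#'
#' Keeps regions whose raw read count strictly exceeds `min_reads`
#' (normalization is applied to reported abundances only, never to this
#' threshold).
#'
#' @param regions tibble with a raw-count column `n_reads`.
#' @param min_reads threshold, strict (default 500).
#' @return the filtered tibble.
#' @export
producers <- function(regions, min_reads = 500) {
  filter(regions, .data$n_reads > min_reads)
}

#' Normalize a count by sample miRNA content
#'
#' Cross-library small-RNA counts are made comparable by scaling to the
#' per-library miRNA total: `count * scale / mirna_total`.
#'
#' @param count raw count(s).
#' @param mirna_total total miRNA reads of the library (must be positive).
#' @param scale scale constant (default 1e6, i.e. counts per million
#'   miRNAs).
#' @return normalized count(s).
#' @export
normalize_by_mirna <- function(count, mirna_total, scale = 1e6) {
  if (mirna_total <= 0) abort("mirna_total must be positive")
  count * scale / mirna_total
}
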