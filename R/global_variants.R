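#' Extract insertion/deletion structural variants from alignment CIGARs
#'
#' Every CIGAR insertion operation of at least `min_sv_len` nt yields one
#' insertion record carrying the inserted sequence (taken from the aligned
#' query); every deletion/skip operation of at least `min_sv_len` nt yields
#' one deletion record carrying the deleted reference slice. Coordinates are
#' 0-based half-open on the reference; an insertion is a point
#' (`end == start`).
#'
#' @param alignments tibble as from [read_alignment_records()], with columns
#'   `sample_id`, `read_id`, `contig`, `ref_start`, `cigar`, `seq`.
#' @param reference named character vector or `DNAStringSet` of reference
#'   contig sequences (needed to extract deleted sequence; may be `NULL` if
#'   no deletions reach `min_sv_len`).
#' @param min_sv_len minimum SV length in nt (default 50, the usual
#'   assembly-comparison SV floor).
#' @return a tibble of SV records: `sample_id`, `read_id`, `contig`, `start`,
#'   `end`, `kind` (`insertion`/`deletion`), `sequence`.
#' @export
extract_sv <- function(alignments, reference = NULL, min_sv_len = 50) {
  if (!is.null(reference)) reference <- as_chr_seqs(reference)
  rows <- pmap(alignments[c("sample_id", "read_id", "contig", "ref_start",
                            "cigar", "seq")],
    function(sample_id, read_id, contig, ref_start, cigar, seq) {
      w <- cigar_walk(cigar, ref_start)
      ins <- w[w$op == "I" & w$len >= min_sv_len, ]
      del <- w[w$op %in% c("D", "N") & w$len >= min_sv_len, ]
      out <- list()
      if (nrow(ins)) {
        if (any(ins$qpos + ins$len > nchar(seq))) {
          abort("CIGAR references positions beyond the read sequence end")
        }
        out$ins <- tibble(
          sample_id = sample_id, read_id = read_id, contig = contig,
          start = ins$rpos, end = ins$rpos, kind = "insertion",
          sequence = substr0(seq, ins$qpos, ins$qpos + ins$len)
        )
      }
      if (nrow(del)) {
        if (is.null(reference) || is.na(reference[contig])) {
          abort("reference sequences required to extract deletion sequence")
        }
        if (any(del$rpos + del$len > nchar(reference[contig]))) {
          abort("CIGAR references positions beyond the reference end")
        }
        out$del <- tibble(
          sample_id = sample_id, read_id = read_id, contig = contig,
          start = del$rpos, end = del$rpos + del$len, kind = "deletion",
          sequence = substr0(reference[[contig]], del$rpos, del$rpos + del$len)
        )
      }
      if (length(out)) bind_rows(out) else NULL
    })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(sample_id = character(), read_id = character(),
                  contig = character(), start = integer(), end = integer(),
                  kind = character(), sequence = character())
  }
  out
}

as_chr_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x))) abort("reference sequences must be named")
  x
}

# Best hit of one sequence against every library entry.
# Ties: highest score, then highest consensus coverage, then family name.
best_library_hit <- function(sequence, lib, scoring = align_scoring()) {
  if (nrow(lib) == 0) abort("empty TE library")
  hits <- map(seq_len(nrow(lib)), function(i) {
    aln <- local_align(sequence, lib$sequence[i], scoring)
    if (is.null(aln)) return(NULL)
    tibble(
      family = lib$name[i],
      identity = percent_identity(aln),
      consensus_coverage = target_coverage(aln, nchar(lib$sequence[i])),
      fragment_length = aln$query_interval[2] - aln$query_interval[1],
      consensus_length = nchar(lib$sequence[i]),
      score = aln$score
    )
  })
  hits <- bind_rows(hits)
  if (!nrow(hits)) return(NULL)
  hits <- arrange(hits, desc(.data$score), desc(.data$consensus_coverage),
                  .data$family)
  hits[1, ]
}

#' Classify structural variants as TE insertions ("global variants")
#'
#' Aligns each SV sequence against every entry of the TE consensus library
#' and reports the best hit. A call is accepted when the hit covers more
#' than `min_coverage` of the consensus and exceeds `min_identity` percent
#' identity (strict inequalities). With both thresholds at 0 every best hit
#' is accepted (the unfiltered mode used for wild-type strains).
#'
#' @param svs tibble from [extract_sv()].
#' @param lib a `te_library` tibble.
#' @param min_coverage minimum consensus-coverage fraction (default 0.80).
#' @param min_identity minimum percent identity (default 80).
#' @param scoring an [align_scoring()] scheme.
#' @return the input tibble plus columns `family` (`"none"` when no hit),
#'   `identity`, `consensus_coverage`, `fragment_length`, `accepted`.
#' @export
classify_sv <- function(svs, lib, min_coverage = 0.80, min_identity = 80,
                        scoring = align_scoring()) {
  if (nrow(lib) == 0) abort("empty TE library")
  res <- map(svs$sequence, function(s) {
    hit <- best_library_hit(s, lib, scoring)
    if (is.null(hit)) {
      return(tibble(family = "none", identity = NA_real_,
                    consensus_coverage = NA_real_,
                    fragment_length = NA_integer_, accepted = FALSE))
    }
    accepted <- (min_coverage == 0 && min_identity == 0) ||
      (hit$consensus_coverage > min_coverage && hit$identity > min_identity)
    tibble(family = hit$family, identity = hit$identity,
           consensus_coverage = hit$consensus_coverage,
           fragment_length = as.integer(hit$fragment_length),
           accepted = accepted)
  })
  bind_cols(svs, bind_rows(res))
}

#' Per-sample, per-family counts of accepted TE insertions
#'
#' @param calls tibble from [classify_sv()].
#' @return tibble with columns `sample_id`, `family`, `n`.
#' @export
copy_table <- function(calls) {
  calls %>%
    filter(.data$accepted, .data$kind == "insertion") %>%
    count(.data$sample_id, .data$family, name = "n")
}

#' Count insertions shared between two samples
#'
#' Accepted insertion calls from the two sets are matched when they have the
#' same family and contig and insertion points within `window` nt; each call
#' is matched at most once, greedily by increasing distance.
#'
#' @param calls_a,calls_b classified call tibbles on the same reference.
#' @param window maximum distance in nt (default 100).
#' @return integer count of shared insertions.
#' @export
shared_insertions <- function(calls_a, calls_b, window = 100) {
  a <- filter(calls_a, .data$accepted, .data$kind == "insertion")
  b <- filter(calls_b, .data$accepted, .data$kind == "insertion")
  if (!nrow(a) || !nrow(b)) return(0L)
  a$.ia <- seq_len(nrow(a)); b$.ib <- seq_len(nrow(b))
  cand <- inner_join(
    a[c(".ia", "contig", "family", "start")],
    b[c(".ib", "contig", "family", "start")],
    by = c("contig", "family"), relationship = "many-to-many"
  ) %>%
    mutate(dist = abs(.data$start.x - .data$start.y)) %>%
    filter(.data$dist <= window) %>%
    arrange(.data$dist)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b)); n <- 0L
  for (i in seq_len(nrow(cand))) {
    ia <- cand$.ia[i]; ib <- cand$.ib[i]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE; n <- n + 1L
    }
  }
  n
}
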