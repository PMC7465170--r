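#' Per-read insertion events and merged MIV candidates
#'
#' Mines CIGAR insertion operations longer than `min_len` nt from long-read
#' versus-assembly alignments; each qualifying operation is a per-read event
#' (position, inserted sequence). Events on the same contig whose positions
#' lie within `merge_window` nt and whose lengths agree to within
#' `min_len_ratio` are merged into a single candidate whose sequence (and
#' position) come from the longest supporting event and whose support counts
#' the merged reads. Support can be a single read: that is the point of
#' minor-variant detection.
#'
#' @param alignments tibble as from [read_alignment_records()] (long reads
#'   mapped to the sample's own assembly).
#' @param min_len events must be strictly longer than this (default 1000 nt).
#' @param merge_window maximum position distance for merging (default 100).
#' @param min_len_ratio minimum short/long length ratio for merging
#'   (default 0.8).
#' @return a tibble of candidates: `contig`, `position` (0-based), `length`,
#'   `sequence`, `read_ids` (list column), `support`, and `events` (list
#'   column with the per-read event coordinates, including the event offset
#'   `qpos` within each supporting read; junction analysis is anchored
#'   there).
#' @export
candidates_from_reads <- function(alignments, min_len = 1000,
                                  merge_window = 100, min_len_ratio = 0.8) {
  ev <- pmap(alignments[c("read_id", "contig", "ref_start", "cigar", "seq")],
    function(read_id, contig, ref_start, cigar, seq) {
      w <- tryCatch(cigar_walk(cigar, ref_start),
                    error = function(e) abort(sprintf(
                      "malformed CIGAR for read %s: %s", read_id,
                      conditionMessage(e))))
      ins <- w[w$op == "I" & w$len > min_len, ]
      if (!nrow(ins)) return(NULL)
      tibble(read_id = read_id, contig = contig, position = ins$rpos,
             length = ins$len, qpos = ins$qpos,
             sequence = substr0(seq, ins$qpos, ins$qpos + ins$len))
    }) %>% bind_rows()
  empty <- tibble(contig = character(), position = integer(),
                  length = integer(), sequence = character(),
                  read_ids = list(), support = integer(), events = list())
  if (!nrow(ev)) return(empty)
  ev <- arrange(ev, .data$contig, .data$position)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    best <- which.max(cur$length)
    tibble(contig = cur$contig[1],
           position = cur$position[best],
           length = cur$length[best],
           sequence = cur$sequence[best],
           read_ids = list(unique(cur$read_id)),
           support = length(unique(cur$read_id)),
           events = list(cur[c("read_id", "position", "qpos", "length")]))
  }
  for (i in seq_len(nrow(ev))) {
    row <- ev[i, ]
    if (is.null(cur)) { cur <- row; next }
    same <- row$contig == cur$contig[nrow(cur)] &&
      (row$position - cur$position[nrow(cur)]) <= merge_window &&
      min(row$length, max(cur$length)) / max(row$length, max(cur$length)) >=
        min_len_ratio
    if (same) cur <- bind_rows(cur, row)
    else { out[[length(out) + 1L]] <- flush(cur); cur <- row }
  }
  out[[length(out) + 1L]] <- flush(cur)
  bind_rows(out)
}

#' MIV acceptance rule
#'
#' The filter cascade for a putative LTR minor insertional variant: percent
#' identity strictly above `min_identity`, consensus coverage of at least
#' `min_coverage` (inclusive), and candidate length exceeding the consensus
#' length by at most `tsd_allowance` nt (18 nt being the largest TSD ever
#' reported to flank an LTR element).
#'
#' @param identity percent identity of the best LTR hit.
#' @param coverage consensus-coverage fraction.
#' @param length_excess candidate length minus consensus length, nt.
#' @param min_identity,min_coverage,tsd_allowance thresholds (defaults 94,
#'   0.90, 18).
#' @return logical.
#' @export
miv_accept <- function(identity, coverage, length_excess,
                       min_identity = 94, min_coverage = 0.90,
                       tsd_allowance = 18) {
  !is.na(identity) & identity > min_identity &
    coverage >= min_coverage & length_excess <= tsd_allowance
}

#' Validate MIV candidates against the LTR consensus subset
#'
#' Assigns each candidate its best-hit LTR family (highest alignment score;
#' ties broken by coverage then name) and applies [miv_accept()].
#'
#' @param candidates tibble from [candidates_from_reads()].
#' @param ltr_lib an LTR-only `te_library` (see [ltr_subset()]).
#' @param min_identity,min_coverage,tsd_allowance see [miv_accept()].
#' @param scoring an [align_scoring()] scheme.
#' @return the candidate tibble plus `family`, `identity`,
#'   `consensus_coverage`, `length_excess`, `accepted`.
#' @export
validate_miv <- function(candidates, ltr_lib, min_identity = 94,
                         min_coverage = 0.90, tsd_allowance = 18,
                         scoring = align_scoring()) {
  if (nrow(ltr_lib) == 0) abort("empty TE library")
  res <- map2(candidates$sequence, candidates$length, function(s, len) {
    hit <- best_library_hit(s, ltr_lib, scoring)
    if (is.null(hit)) {
      return(tibble(family = "none", identity = NA_real_,
                    consensus_coverage = NA_real_,
                    length_excess = NA_integer_, accepted = FALSE))
    }
    excess <- len - hit$consensus_length
    tibble(family = hit$family, identity = hit$identity,
           consensus_coverage = hit$consensus_coverage,
           length_excess = as.integer(excess),
           accepted = miv_accept(hit$identity, hit$consensus_coverage, excess,
                                 min_identity, min_coverage, tsd_allowance))
  })
  bind_cols(candidates, bind_rows(res))
}

#' Histogram of read support over accepted MIV calls
#'
#' @param calls tibble from [validate_miv()].
#' @return tibble with columns `support`, `n`; `sum(n)` equals the number of
#'   accepted calls.
#' @export
support_histogram <- function(calls) {
  calls %>%
    filter(.data$accepted) %>%
    count(.data$support, name = "n")
}

#' Per-sample, per-family accepted MIV counts
#'
#' @param calls tibble from [validate_miv()] carrying a `sample_id` column.
#' @return tibble with columns `sample_id`, `family`, `n`.
#' @export
family_count_matrix <- function(calls) {
  calls %>%
    filter(.data$accepted) %>%
    count(.data$sample_id, .data$family, name = "n")
}
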