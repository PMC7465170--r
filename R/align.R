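#' Alignment scoring scheme
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open -5, gap extend -2
#' (a gap of length L costs 5 + 2L). `N` is scored as a mismatch against
#' every base including itself, so ambiguous positions never contribute
#' positive score.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores (penalties
#'   negative).
#' @return a list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

subst_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

# Run-length ops from the gapped pattern/subject strings of an alignment.
# insertion = base present in query but not target; deletion = the reverse.
ops_from_gapped <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  kind <- ifelse(pc == "-", "deletion",
          ifelse(sc == "-", "insertion",
          ifelse(pc == sc, "match", "mismatch")))
  r <- rle(kind)
  tibble(op = r$values, len = r$lengths)
}

new_alignment <- function(query_id, target_id, query_interval, target_interval,
                          strand, ops, n_matches, n_columns, score,
                          pattern = NULL, subject = NULL, edit_distance = NULL) {
  structure(
    list(query_id = query_id, target_id = target_id,
         query_interval = as.integer(query_interval),
         target_interval = as.integer(target_interval),
         strand = strand, ops = ops,
         n_matches = as.integer(n_matches),
         n_columns = as.integer(n_columns),
         score = score, pattern = pattern, subject = subject,
         edit_distance = edit_distance),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> %s[%d,%d) vs %s[%d,%d) strand %s  score %.1f  %d/%d matched cols%s\n",
    x$query_id, x$query_interval[1], x$query_interval[2],
    x$target_id, x$target_interval[1], x$target_interval[2],
    x$strand, x$score, x$n_matches, x$n_columns,
    if (!is.null(x$edit_distance)) sprintf("  edit dist %d", x$edit_distance) else ""
  ))
  invisible(x)
}

#' @export
#' @method tidy pairwise_alignment
tidy.pairwise_alignment <- function(x, ...) {
  tibble(
    query_id = x$query_id, target_id = x$target_id,
    query_start = x$query_interval[1], query_end = x$query_interval[2],
    target_start = x$target_interval[1], target_end = x$target_interval[2],
    strand = x$strand, n_matches = x$n_matches, n_columns = x$n_columns,
    score = x$score,
    edit_distance = if (is.null(x$edit_distance)) NA_integer_ else x$edit_distance
  )
}

one_local <- function(query, target, mat, scoring, strand, query_len) {
  pa <- Biostrings::pairwiseAlignment(
    query, target, type = "local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  qs <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  qe <- Biostrings::end(Biostrings::pattern(pa))
  if (strand == "-") {
    # report against forward coordinates of the original query
    tmp <- query_len - qs
    qs <- query_len - qe
    qe <- tmp
  }
  new_alignment(
    query_id = "query", target_id = "target",
    query_interval = c(qs, qe),
    target_interval = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
                        Biostrings::end(Biostrings::subject(pa))),
    strand = strand,
    ops = ops_from_gapped(p, s),
    n_matches = Biostrings::nmatch(pa),
    n_columns = nchar(p),
    score = Biostrings::score(pa),
    pattern = p, subject = s
  )
}

#' Best local alignment of a query against a target, both strands
#'
#' Smith–Waterman-style local alignment under an affine-gap scoring scheme.
#' Both strands of the query are searched; the higher-scoring strand wins,
#' with ties broken by longer target span, then leftmost target start, then
#' the `+` strand. Reverse-strand hits are reported against forward target
#' coordinates with `strand = "-"`; the query interval is given in original
#' (forward) query coordinates.
#'
#' @param query,target nucleotide strings over `{A,C,G,T,N}`.
#' @param scoring an [align_scoring()] scheme.
#' @return a `pairwise_alignment` object, or `NULL` ("no hit") when no
#'   alignment scores above 0.
#' @export
#' @examples
#' aln <- local_align("ACGTACGTAC", "ACGTTCGTAC")
#' percent_identity(aln)
local_align <- function(query, target, scoring = align_scoring()) {
  query <- check_seq(query, "query")
  target <- check_seq(target, "target")
  if (nchar(query) == 0 || nchar(target) == 0) abort("empty input sequence")
  mat <- subst_matrix(scoring)
  fwd <- one_local(query, target, mat, scoring, "+", nchar(query))
  rev <- one_local(revcomp(query), target, mat, scoring, "-", nchar(query))
  best <- pick_alignment(fwd, rev)
  if (best$score <= 0) return(NULL)
  best
}

pick_alignment <- function(fwd, rev) {
  key <- function(a) c(a$score,
                       a$target_interval[2] - a$target_interval[1],
                       -a$target_interval[1],
                       if (a$strand == "+") 1 else 0)
  kf <- key(fwd); kr <- key(rev)
  for (i in seq_along(kf)) {
    if (kf[i] > kr[i]) return(fwd)
    if (kf[i] < kr[i]) return(rev)
  }
  fwd
}

#' Percent identity of an alignment
#'
#' `100 * n_matches / n_columns`, where the denominator counts every aligned
#' column including gap columns (BLAST-style identity).
#'
#' @param aln a `pairwise_alignment`.
#' @return a percentage in `(0, 100]`.
#' @export
percent_identity <- function(aln) {
  if (is.null(aln) || aln$n_columns == 0) abort("zero-column alignment")
  100 * aln$n_matches / aln$n_columns
}

#' Fraction of the target covered by an alignment
#'
#' @param aln a `pairwise_alignment` whose target interval lies on the
#'   sequence of length `target_len`.
#' @param target_len full target (e.g. TE consensus) length in nt.
#' @return a fraction in `(0, 1]`.
#' @export
target_coverage <- function(aln, target_len) {
  if (target_len <= 0) abort("target_len must be positive")
  span <- aln$target_interval[2] - aln$target_interval[1]
  if (span > target_len) abort("target interval exceeds target_len")
  span / target_len
}

#' Minimum-edit-distance global alignment
#'
#' End-to-end alignment of `a` to `b` under unit edit costs (Levenshtein).
#' Used by the TSD error-correction step, which needs the column-by-column
#' correspondence, not just the distance.
#'
#' @param a,b nucleotide strings.
#' @return a `pairwise_alignment` with an `edit_distance` field and the
#'   gapped `pattern` (`a`) / `subject` (`b`) strings.
#' @export
global_edit_align <- function(a, b) {
  a <- check_seq(a, "a"); b <- check_seq(b, "b")
  if (nchar(a) == 0 || nchar(b) == 0) abort("empty input sequence")
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1L, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 0L
  m["N", "N"] <- -1L
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 1
  )
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  ops <- ops_from_gapped(p, s)
  new_alignment(
    query_id = "a", target_id = "b",
    query_interval = c(0L, nchar(a)),
    target_interval = c(0L, nchar(b)),
    strand = "+", ops = ops,
    n_matches = Biostrings::nmatch(pa),
    n_columns = nchar(p),
    score = Biostrings::score(pa),
    pattern = p, subject = s,
    edit_distance = as.integer(-Biostrings::score(pa))
  )
}
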