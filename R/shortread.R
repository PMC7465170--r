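#' Discordant pairs pointing at non-reference TE insertions
#'
#' Scans per-mate alignment records of paired-end reads mapped jointly to
#' the reference genome and the TE consensus sequences. A pair is emitted
#' when exactly one mate maps to the genome, the other maps to a TE
#' sequence, and the pair has no concordant genome mapping. Orphan records
#' (missing mate) are skipped with a message.
#'
#' @param records tibble as from [read_pair_records()]: columns `read_id`,
#'   `mate`, `ref`, `pos` (0-based), `strand`, `mapped`, `proper_pair`.
#' @param te_names character vector of TE family names; any other `ref` is
#'   a genome contig.
#' @return a tibble of discordant pairs: `read_id`, `contig`, `genome_pos`,
#'   `te_family`, `genome_mate_strand`.
#' @export
find_discordant <- function(records, te_names) {
  records <- filter(records, .data$mapped)
  records$is_te <- records$ref %in% te_names
  grp <- split(seq_len(nrow(records)), records$read_id)
  n_orphan <- 0L
  out <- map(grp, function(idx) {
    r <- records[idx, ]
    if (length(unique(r$mate)) < 2L) { n_orphan <<- n_orphan + 1L; return(NULL) }
    if (any(r$proper_pair)) return(NULL)
    g <- r[!r$is_te, ]; t <- r[r$is_te, ]
    if (nrow(g) != 1L || nrow(t) != 1L) return(NULL)
    tibble(read_id = r$read_id[1], contig = g$ref, genome_pos = g$pos,
           te_family = t$ref, genome_mate_strand = g$strand)
  })
  if (n_orphan > 0) {
    rlang::inform(sprintf("skipped %d orphan record(s) without a mapped mate",
                          n_orphan))
  }
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(read_id = character(), contig = character(),
                  genome_pos = integer(), te_family = character(),
                  genome_mate_strand = character())
  }
  arrange(out, .data$contig, .data$te_family, .data$genome_pos)
}

#' Cluster discordant pairs into insertion calls
#'
#' Single-linkage clustering of genome-mate positions per (contig, TE
#' family): sorted positions are chained while consecutive members are no
#' further apart than `max_gap` nt (inclusive). Each cluster is interpreted
#' as one insertion whose position is the mean of its member positions
#' (rounded to the nearest integer) and whose strength is its read count.
#' Pairs pointing at different families never merge, matching the
#' per-family insertion counts downstream.
#'
#' @param pairs tibble from [find_discordant()].
#' @param max_gap maximum within-cluster neighbour distance, nt
#'   (default 100).
#' @return a tibble of clusters: `contig`, `te_family`, `position`,
#'   `n_reads`, `member_positions` (list column).
#' @export
cluster_pairs <- function(pairs, max_gap = 100) {
  empty <- tibble(contig = character(), te_family = character(),
                  position = integer(), n_reads = integer(),
                  member_positions = list())
  if (!nrow(pairs)) return(empty)
  pairs %>%
    arrange(.data$contig, .data$te_family, .data$genome_pos) %>%
    group_by(.data$contig, .data$te_family) %>%
    group_modify(function(d, key) {
      pos <- d$genome_pos
      brk <- cumsum(c(0L, as.integer(diff(pos) > max_gap)))
      tibble(
        position = as.integer(tapply(pos, brk, function(p) round_half_up(mean(p)))),
        n_reads = as.integer(tapply(pos, brk, length)),
        member_positions = unname(split(pos, brk))
      )
    }) %>%
    ungroup()
}

#' Keep clusters with sufficient read support
#'
#' @param clusters tibble from [cluster_pairs()].
#' @param min_reads minimum supporting reads, inclusive (default 50).
#' @return the filtered cluster tibble.
#' @export
filter_clusters <- function(clusters, min_reads = 50) {
  filter(clusters, .data$n_reads >= min_reads)
}
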