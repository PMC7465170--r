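#' ONT-like per-base error profile
#'
#' Per-base probabilities of substitution, insertion and deletion applied
#' independently at each template base. Rates must lie in `[0, 0.2]` with a
#' total below 0.5.
#'
#' @param substitution,insertion,deletion per-base probabilities.
#' @return a list of class `error_profile`.
#' @seealso [ont_error_profile()] for a total-rate shorthand.
#' @export
error_profile <- function(substitution = 0, insertion = 0, deletion = 0) {
  rates <- c(substitution, insertion, deletion)
  if (any(rates < 0 | rates > 0.2) || sum(rates) >= 0.5) {
    abort("rates must lie in [0, 0.2] with total < 0.5")
  }
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion), class = "error_profile")
}

#' Split a total error rate into an ONT-like profile
#'
#' 40% substitutions, 30% insertions, 30% deletions of the total rate —
#' the rough composition of nanopore base errors.
#'
#' @param total total per-base error rate (e.g. 0.05 for 5%).
#' @return an [error_profile()].
#' @export
ont_error_profile <- function(total) {
  error_profile(substitution = 0.4 * total, insertion = 0.3 * total,
                deletion = 0.3 * total)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Random genome sequence
#'
#' I.i.d. bases at the stated GC content; reproducible for a fixed seed.
#'
#' @param length genome length in nt.
#' @param gc GC fraction (default 0.42, fly-like).
#' @param seed optional integer seed.
#' @return a nucleotide string.
#' @export
random_genome <- function(length, gc = 0.42, seed = NULL) {
  if (length < 1) abort("length must be >= 1")
  if (gc < 0 || gc > 1) abort("gc must lie in [0, 1]")
  with_seed_if(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p[BASES]),
          collapse = "")
  })
}

#' Random synthetic TE consensus library
#'
#' Generates distinct random consensus sequences for testing; real analyses
#' use a curated library via [load_te_library()].
#'
#' @param n_families number of families.
#' @param group TE group label for all families (default `"LTR"`).
#' @param length_range consensus length range in nt (default 1500--2500).
#' @param tsd_size expected TSD size for all families (default 4).
#' @param gc GC fraction.
#' @param seed optional integer seed.
#' @return a `te_library` tibble.
#' @export
random_te_library <- function(n_families = 6, group = "LTR",
                              length_range = c(1500, 2500), tsd_size = 4,
                              gc = 0.42, seed = NULL) {
  with_seed_if(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_families,
                   replace = TRUE)
    te_library_tbl(
      name = sprintf("%s_fam%02d", tolower(group), seq_len(n_families)),
      group = group,
      sequence = vapply(lens, function(L) random_genome(L, gc), ""),
      tsd_size = tsd_size
    )
  })
}

#' Implant TE copies with target site duplications into a genome
#'
#' At each site the `k`-nt genomic target (where `k` is the family's
#' expected TSD size) is duplicated so the final locus reads
#' `[target][TE][target]`, as produced by the staggered cuts of
#' integration. Fixed insertions are written into the returned assembly;
#' minor insertions are recorded in the truth table with their population
#' frequency and applied only to the matching fraction of simulated read
#' templates (they are too rare to enter an assembly), never to the
#' assembly itself.
#'
#' @param genome base genome string (becomes the empty-site allele).
#' @param lib a `te_library` with known `tsd_size` for the used families.
#' @param sites tibble with columns `position` (0-based, in base-genome
#'   coordinates), `family`, `class` (`"fixed"` or `"minor"`) and
#'   `frequency` (fraction, used for minor sites; `NA` for fixed).
#' @return a list of class `te_sim`: `assembly` (genome with fixed
#'   insertions), `base_genome`, `lib`, and `truth` — a tibble with
#'   `contig`, `position`, `assembly_position` (the empty-site coordinate
#'   on the assembly; insertion point of minor variants), `family`, `tsd`,
#'   `length`, `class`, `frequency`.
#' @export
implant_insertions <- function(genome, lib, sites) {
  if (!nrow(sites)) {
    return(structure(list(assembly = genome, base_genome = genome, lib = lib,
                          truth = tibble(contig = character(),
                                         position = integer(),
                                         assembly_position = integer(),
                                         family = character(), tsd = character(),
                                         length = integer(), class = character(),
                                         frequency = double())),
                     class = "te_sim"))
  }
  sites <- arrange(sites, .data$position)
  if (!"frequency" %in% names(sites)) sites$frequency <- NA_real_
  idx <- match(sites$family, lib$name)
  if (anyNA(idx)) abort("site family not present in the library")
  k <- lib$tsd_size[idx]
  if (anyNA(k)) abort("families used for implantation need a known tsd_size")
  te_seq <- lib$sequence[idx]
  G <- nchar(genome)
  if (any(sites$position < k | sites$position + k > G)) {
    abort("sites must lie at least tsd_size away from the contig ends")
  }
  if (any(diff(sites$position) < k[-length(k)])) {
    abort("overlapping sites: targets must not overlap after insertion")
  }
  truth <- tibble(
    contig = "chr1",
    position = as.integer(sites$position),
    assembly_position = NA_integer_,
    family = sites$family,
    tsd = substr0(rep(genome, nrow(sites)), sites$position,
                  sites$position + k),
    length = nchar(te_seq),
    class = sites$class,
    frequency = sites$frequency
  )
  # assemble: fixed insertions shift downstream coordinates by length + k
  offset <- 0L
  pieces <- character(0)
  last <- 0L
  for (i in seq_len(nrow(truth))) {
    truth$assembly_position[i] <- truth$position[i] + offset
    if (truth$class[i] == "fixed") {
      p <- truth$position[i]
      pieces <- c(pieces, substr0(genome, last, p + k[i]), te_seq[i])
      last <- p  # duplicate the target: resume at p, not p + k
      offset <- offset + truth$length[i] + k[i]
    }
  }
  pieces <- c(pieces, substr0(genome, last, G))
  structure(list(assembly = paste(pieces, collapse = ""),
                 base_genome = genome, lib = lib, truth = truth),
            class = "te_sim")
}

apply_error_profile <- function(seq, profile) {
  if (profile$substitution == 0 && profile$insertion == 0 &&
      profile$deletion == 0) {
    return(seq)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- stats::runif(n)
  del <- u < profile$deletion
  sub <- !del & u < profile$deletion + profile$substitution
  if (any(sub)) {
    # substitute with a uniformly chosen different base
    ch[sub] <- vapply(ch[sub], function(b) sample(setdiff(BASES, b), 1L), "",
                      USE.NAMES = FALSE)
  }
  ins <- stats::runif(n) < profile$insertion
  if (any(ins)) {
    ch[ins] <- paste0(ch[ins], sample(BASES, sum(ins), replace = TRUE))
  }
  paste(ch[!del], collapse = "")
}

#' Simulate ONT-like long reads from a TE simulation
#'
#' Read starts are uniform over the assembly; lengths follow a gamma
#' distribution (shape 2, mean `mean_len`), truncated at `min_len` and the
#' contig end. Reads overlapping a minor-insertion site carry that
#' insertion with its population frequency (the template is spliced per
#' read). Strands are random; errors follow the profile.
#'
#' @param sim a `te_sim` from [implant_insertions()].
#' @param coverage fold coverage of the assembly.
#' @param mean_len mean read length in nt (default 8000).
#' @param min_len minimum read length (default 300).
#' @param profile an [error_profile()].
#' @param seed optional integer seed.
#' @return a tibble of reads: `read_id`, `seq`, `start` (assembly, 0-based),
#'   `length` (error-free template length), `strand`, `carries` (list of
#'   truth-row indices of carried minor insertions).
#' @export
long_reads <- function(sim, coverage, mean_len = 8000, min_len = 300,
                       profile = error_profile(), seed = NULL) {
  if (coverage <= 0) abort("coverage must be positive")
  with_seed_if(seed, {
    G <- nchar(sim$assembly)
    n_reads <- ceiling(coverage * G / mean_len)
    lens <- pmax(min_len,
                 round(stats::rgamma(n_reads, shape = 2, scale = mean_len / 2)))
    starts <- floor(stats::runif(n_reads, 0, pmax(1, G - lens)))
    minors <- which(sim$truth$class == "minor")
    rows <- map(seq_len(n_reads), function(i) {
      s <- starts[i]; L <- min(lens[i], G - s)
      inside <- minors[sim$truth$assembly_position[minors] > s &
                       sim$truth$assembly_position[minors] < s + L]
      carried <- inside[stats::runif(length(inside)) <
                          sim$truth$frequency[inside]]
      tmpl <- read_template(sim, s, L, carried)
      strand <- sample(c("+", "-"), 1L)
      out <- if (strand == "-") revcomp(tmpl) else tmpl
      tibble(read_id = sprintf("read%05d", i),
             seq = apply_error_profile(out, profile),
             start = s, length = nchar(tmpl), strand = strand,
             carries = list(carried))
    })
    bind_rows(rows)
  })
}

# error-free template of a read: assembly span [s, s+L) with the carried
# minor insertions spliced in ([target][TE][target] at each site)
read_template <- function(sim, s, L, carried) {
  if (!length(carried)) return(substr0(sim$assembly, s, s + L))
  carried <- carried[order(sim$truth$assembly_position[carried])]
  k <- sim$lib$tsd_size[match(sim$truth$family[carried], sim$lib$name)]
  te <- sim$lib$sequence[match(sim$truth$family[carried], sim$lib$name)]
  pieces <- character(0)
  last <- s
  for (j in seq_along(carried)) {
    ap <- sim$truth$assembly_position[carried[j]]
    pieces <- c(pieces, substr0(sim$assembly, last, ap + k[j]), te[j])
    last <- ap
  }
  pieces <- c(pieces, substr0(sim$assembly, last, s + L))
  paste(pieces, collapse = "")
}

#' Simulate paired-end short reads over a TE simulation
#'
#' Fragments are drawn uniformly from the assembly (which carries the fixed
#' insertions); mates are the fragment ends, the second mate
#' reverse-complemented. Each mate is annotated against the truth: fully
#' within a TE copy (`te`), fully outside (`genome`), or spanning a
#' junction (`junction`). Pairs with one genome mate and one TE mate are
#' the truth-discordant pairs the short-read caller should recover.
#'
#' @param sim a `te_sim` from [implant_insertions()].
#' @param n_pairs number of pairs.
#' @param read_len mate length in nt (default 100).
#' @param insert_mean,insert_sd fragment length distribution (defaults 400,
#'   40); `insert_mean` must exceed `2 * read_len`.
#' @param profile an [error_profile()].
#' @param seed optional integer seed.
#' @return a tibble: `pair_id`, `seq1`, `seq2`, `frag_start`, `frag_len`
#'   (assembly coordinates), `loc1`, `loc2` (mate annotation), `te_family`
#'   (family of a TE-located mate or `NA`), `ref_pos1`, `ref_pos2`
#'   (base-genome projection of genome-located mates, else `NA`),
#'   `truth_discordant`.
#' @export
paired_reads <- function(sim, n_pairs, read_len = 100, insert_mean = 400,
                         insert_sd = 40, profile = error_profile(),
                         seed = NULL) {
  if (insert_mean <= 2 * read_len) abort("insert_mean must exceed 2*read_len")
  with_seed_if(seed, {
    G <- nchar(sim$assembly)
    fixed <- sim$truth[sim$truth$class == "fixed", ]
    k <- sim$lib$tsd_size[match(fixed$family, sim$lib$name)]
    te_start <- fixed$assembly_position + k       # TE interval on assembly
    te_end <- te_start + fixed$length
    shift_before <- cumsum(c(0L, fixed$length + k))[seq_len(nrow(fixed))]
    lens <- pmax(2 * read_len,
                 round(stats::rnorm(n_pairs, insert_mean, insert_sd)))
    starts <- floor(stats::runif(n_pairs, 0, pmax(1, G - lens)))
    lens <- pmin(lens, G - starts)
    # vectorized mate annotation against the fixed-TE intervals
    annotate <- function(a, b) {  # mate intervals [a, b) on the assembly
      if (!nrow(fixed)) {
        return(list(loc = rep("genome", length(a)),
                    family = rep(NA_character_, length(a)),
                    ref = as.integer(a)))
      }
      in_te <- outer(a, te_start, ">=") & outer(b, te_end, "<=")
      touch <- outer(a, te_end, "<") & outer(b, te_start, ">")
      inside <- rowSums(in_te) > 0
      junction <- !inside & rowSums(touch) > 0
      loc <- ifelse(inside, "te", ifelse(junction, "junction", "genome"))
      fam_idx <- apply(in_te | touch, 1, function(x) {
        i <- which(x); if (length(i)) i[1] else NA_integer_
      })
      n_before <- rowSums(outer(a, te_end, ">="))
      shift <- ifelse(n_before > 0,
                      shift_before[pmax(n_before, 1)] +
                        fixed$length[pmax(n_before, 1)] + k[pmax(n_before, 1)],
                      0L)
      list(loc = loc,
           family = ifelse(is.na(fam_idx), NA_character_,
                           fixed$family[fam_idx]),
           ref = ifelse(loc == "genome", as.integer(a - shift), NA_integer_))
    }
    a1 <- annotate(starts, starts + read_len)
    a2 <- annotate(starts + lens - read_len, starts + lens)
    m1 <- substr0(sim$assembly, starts, starts + read_len)
    m2 <- revcomp(substr0(sim$assembly, starts + lens - read_len,
                          starts + lens))
    if (profile$substitution + profile$insertion + profile$deletion > 0) {
      m1 <- vapply(m1, apply_error_profile, "", profile, USE.NAMES = FALSE)
      m2 <- vapply(m2, apply_error_profile, "", profile, USE.NAMES = FALSE)
    }
    tibble(pair_id = sprintf("pair%06d", seq_len(n_pairs)),
           seq1 = m1, seq2 = m2,
           frag_start = as.integer(starts), frag_len = as.integer(lens),
           loc1 = a1$loc, loc2 = a2$loc,
           te_family = ifelse(a1$loc == "te", a1$family,
                              ifelse(a2$loc == "te", a2$family,
                                     NA_character_)),
           ref_pos1 = a1$ref, ref_pos2 = a2$ref,
           truth_discordant = (a1$loc == "genome" & a2$loc == "te") |
                              (a1$loc == "te" & a2$loc == "genome"))
  })
}

#' Convert simulated pair truth into detector input records
#'
#' Builds the per-mate record tibble consumed by [find_discordant()]
#' directly from the truth annotation of [paired_reads()] (an idealized,
#' error-free mapper): genome mates map at their reference-projected
#' position, TE mates to their family, junction mates are unmapped, and
#' pairs with both mates on the genome are flagged concordant. The genome
#' mate's recorded position is its TE-facing (inner) coordinate — the
#' junction-proximal alignment edge a caller derives from the mate strand —
#' so that clusters of discordant pairs localize at the insertion point.
#'
#' @param pairs tibble from [paired_reads()].
#' @param read_len mate length used in the simulation.
#' @return a record tibble (`read_id`, `mate`, `ref`, `pos`, `strand`,
#'   `mapped`, `proper_pair`).
#' @export
pair_records_from_truth <- function(pairs, read_len = 100) {
  proper <- pairs$loc1 == "genome" & pairs$loc2 == "genome"
  one <- function(mate, loc, ref_pos, strand) {
    inner <- ifelse(loc == "genome" & strand == "+",
                    ref_pos + as.integer(read_len),  # forward mate faces right
                    ref_pos)
    tibble(read_id = pairs$pair_id, mate = mate,
           ref = dplyr::case_match(loc, "genome" ~ "chr1",
                                   "te" ~ pairs$te_family,
                                   "junction" ~ NA_character_),
           pos = ifelse(loc == "genome", as.integer(inner), NA_integer_),
           strand = strand,
           mapped = loc != "junction",
           proper_pair = proper)
  }
  bind_rows(one(1L, pairs$loc1, pairs$ref_pos1, "+"),
            one(2L, pairs$loc2, pairs$ref_pos2, "-")) %>%
    arrange(.data$read_id, .data$mate)
}

#' Write simulated reads to FASTA/FASTQ
#'
#' @param reads tibble with `read_id` and `seq` columns.
#' @param path output path.
#' @param quality_char constant per-base quality for FASTQ (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+",
                           strrep(quality_char, nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
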