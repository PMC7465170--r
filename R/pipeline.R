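#' Map sequences with minimap2 and load the primary records
#'
#' Thin wrapper around the minimap2 command-line mapper (which must be on
#' the `PATH`), used for assembly-versus-reference and long-read-versus-
#' assembly alignment. The SAM output is loaded with
#' [read_alignment_records()]; record sequences are reference-oriented, as
#' stored in SAM.
#'
#' @param reference_fasta,query path to the reference FASTA and the query
#'   FASTA/FASTQ.
#' @param preset a minimap2 preset, e.g. `"asm5"` (assembly-to-reference)
#'   or `"map-ont"` (nanopore reads).
#' @param sample_id label for the records.
#' @return tibble of alignment records.
#' @export
minimap2_records <- function(reference_fasta, query, preset = "map-ont",
                             sample_id = "sample") {
  if (Sys.which("minimap2") == "") {
    abort("minimap2 not found on PATH")
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  status <- system2("minimap2",
                    c("-a", "-x", preset, "--secondary=no",
                      shQuote(reference_fasta), shQuote(query)),
                    stdout = sam, stderr = FALSE)
  if (status != 0) abort("minimap2 failed")
  read_alignment_records(sam, sample_id)
}

# Junction analysis for one supporting read of an MIV call, anchored at the
# read's own insertion event: the read is cropped around the event before the
# consensus is located, so that other copies of the same family elsewhere in
# a long read cannot capture the span.
tsd_for_read <- function(read_seq, qpos, ev_len, cons, k, empty, site,
                         flank = 30, margin = 500) {
  crop0 <- max(0, qpos - margin)
  crop <- substr0(read_seq, crop0, min(nchar(read_seq), qpos + ev_len + margin))
  span <- te_span_in_read(crop, cons)
  list(auto = detect_tsd_auto(crop, span, k, flank = flank),
       corrected = detect_tsd_corrected(crop, span, empty, site, k,
                                        flank = flank))
}

match_calls_to_truth <- function(calls, truth, pos_col, window = 50) {
  if (!nrow(calls)) return(rep(FALSE, nrow(truth)))
  vapply(seq_len(nrow(truth)), function(i) {
    any(calls$family == truth$family[i] &
        abs(calls[[pos_col]] - truth[[if (pos_col == "start") "position" else
                                      "assembly_position"]][i]) <= window)
  }, logical(1))
}

#' End-to-end recovery benchmark on synthetic data
#'
#' Simulates a genome with fixed and minor LTR insertions (family-specific
#' TSDs implanted), then runs the three long-read stages and scores them
#' against the simulation truth: the global stage (assembly vs reference)
#' must recover the fixed insertions, the MIV stage (reads vs assembly)
#' the minor ones, and the junction stage must recover the implanted TSDs
#' from the supporting reads, in automatic and in empty-site corrected
#' mode.
#'
#' Defaults are the package's standard validation conditions: a 100-kb
#' genome, a 6-family LTR library (1.5--2.5 kb consensus, 4-nt TSDs),
#' 5 fixed + 3 minor insertions at 10% population frequency, and 30x
#' long reads of mean length 8 kb.
#'
#' @param seed integer seed driving every random draw.
#' @param profile an [error_profile()] for the long reads.
#' @param genome_len,n_fixed,n_minor,minor_frequency,coverage,mean_len
#'   simulation conditions.
#' @return a list: `global_recall`, `miv_recall`, `tsd_auto_recall`,
#'   `tsd_corrected_recall` (each in `[0,1]`), the underlying counts, and
#'   the per-stage call tibbles.
#' @export
run_synthetic_benchmark <- function(seed = 1, profile = error_profile(),
                                    genome_len = 1e5, n_fixed = 5,
                                    n_minor = 3, minor_frequency = 0.1,
                                    coverage = 30, mean_len = 8000) {
  lib <- random_te_library(6, "LTR", c(1500, 2500), tsd_size = 4,
                           seed = seed)
  genome <- random_genome(genome_len, seed = seed + 1)
  n_sites <- n_fixed + n_minor
  sites <- with_seed_if(seed + 2, {
    # well-separated sites so insertions never interact within one read
    pos <- sort(sample(seq(3000, genome_len - 3000, by = 10), n_sites))
    while (any(diff(pos) < 6000)) {
      pos <- sort(sample(seq(3000, genome_len - 3000, by = 10), n_sites))
    }
    cls <- sample(c(rep("fixed", n_fixed), rep("minor", n_minor)))
    tibble(position = pos, family = sample(lib$name, n_sites, replace = TRUE),
           class = cls,
           frequency = ifelse(cls == "minor", minor_frequency, NA_real_))
  })
  sim <- implant_insertions(genome, lib, sites)
  tdir <- tempfile("tevbench"); dir.create(tdir)
  on.exit(unlink(tdir, recursive = TRUE))
  ref_fa <- file.path(tdir, "reference.fa")
  asm_fa <- file.path(tdir, "assembly.fa")
  write_fasta(c(chr1 = sim$base_genome), ref_fa)
  write_fasta(c(chr1 = sim$assembly), asm_fa)

  # --- global stage: assembly vs reference ---
  aln_global <- minimap2_records(ref_fa, asm_fa, preset = "asm5",
                                 sample_id = "sim")
  svs <- extract_sv(aln_global, reference = c(chr1 = sim$base_genome))
  global_calls <- classify_sv(svs, lib)
  fixed_truth <- sim$truth[sim$truth$class == "fixed", ]
  acc_glob <- filter(global_calls, .data$accepted, .data$kind == "insertion")
  global_hit <- match_calls_to_truth(acc_glob, fixed_truth, "start")

  # --- MIV stage: long reads vs assembly ---
  reads <- long_reads(sim, coverage = coverage, mean_len = mean_len,
                      profile = profile, seed = seed + 3)
  fq <- file.path(tdir, "reads.fastq")
  write_reads_fastq(reads, fq)
  aln_reads <- minimap2_records(asm_fa, fq, preset = "map-ont",
                                sample_id = "sim")
  cands <- candidates_from_reads(aln_reads)
  miv_calls <- validate_miv(cands, ltr_subset(lib))
  minor_truth <- sim$truth[sim$truth$class == "minor", ]
  acc_miv <- filter(miv_calls, .data$accepted)
  miv_hit <- vapply(seq_len(nrow(minor_truth)), function(i) {
    any(acc_miv$family == minor_truth$family[i] &
        abs(acc_miv$position - minor_truth$assembly_position[i]) <= 50)
  }, logical(1))

  # --- TSD stage: supporting reads of matched accepted MIV calls ---
  seq_by_read <- stats::setNames(aln_reads$seq, aln_reads$read_id)
  tsd_rows <- list()
  for (i in seq_len(nrow(acc_miv))) {
    j <- which(minor_truth$family == acc_miv$family[i] &
               abs(minor_truth$assembly_position - acc_miv$position[i]) <= 50)
    if (!length(j)) next
    truth_row <- minor_truth[j[1], ]
    k <- lib$tsd_size[match(truth_row$family, lib$name)]
    cons <- lib[lib$name == acc_miv$family[i], ]
    ap <- truth_row$assembly_position
    win0 <- max(0, ap - 100)
    empty <- substr0(sim$assembly, win0, min(nchar(sim$assembly), ap + 100 + k))
    site <- ap - win0
    events <- acc_miv$events[[i]]
    for (e in seq_len(nrow(events))) {
      rid <- events$read_id[e]
      res <- tryCatch({
        r <- tsd_for_read(seq_by_read[[rid]], events$qpos[e],
                          events$length[e], cons, k, empty, site)
        tibble(read_id = rid, family = truth_row$family,
               truth_tsd = truth_row$tsd,
               auto_found = r$auto$found, auto_tsd = r$auto$tsd,
               corrected_found = r$corrected$found,
               corrected_tsd = r$corrected$tsd)
      }, error = function(err) NULL)  # insufficient flank / TE not located
      if (!is.null(res)) tsd_rows[[length(tsd_rows) + 1L]] <- res
    }
  }
  tsd_tbl <- bind_rows(tsd_rows)
  auto_ok <- corr_ok <- logical(0)
  if (nrow(tsd_tbl)) {
    auto_ok <- tsd_tbl$auto_found & tsd_tbl$auto_tsd == tsd_tbl$truth_tsd
    corr_ok <- tsd_tbl$corrected_found &
      tsd_tbl$corrected_tsd == tsd_tbl$truth_tsd
  }

  list(
    global_recall = mean(global_hit),
    miv_recall = mean(miv_hit),
    tsd_auto_recall = if (length(auto_ok)) mean(auto_ok) else NA_real_,
    tsd_corrected_recall = if (length(corr_ok)) mean(corr_ok) else NA_real_,
    n_fixed = nrow(fixed_truth), n_fixed_recovered = sum(global_hit),
    n_minor = nrow(minor_truth), n_minor_recovered = sum(miv_hit),
    min_miv_support = if (nrow(acc_miv)) min(acc_miv$support) else NA_integer_,
    n_tsd_reads = nrow(tsd_tbl),
    truth = sim$truth, global_calls = global_calls, miv_calls = miv_calls,
    tsd_results = tsd_tbl
  )
}

# effective analysis parameters embedded in reports (paths-only keys such as
# out_dir are not part of the analysis and would break reproducibility checks)
cfg_params <- function(config) {
  config[sort(setdiff(names(config), "out_dir"))]
}

write_report_tsv <- function(df, path, params = list(), version = TRUE) {
  hdr <- character(0)
  if (version) {
    hdr <- sprintf("#tevariant=%s",
                   as.character(utils::packageVersion("tevariant")))
  }
  hdr <- c(hdr, sprintf("#%s=%s", names(params),
                        vapply(params, function(x) paste(format(x), collapse = ","), "")))
  writeLines(hdr, path)
  df <- mutate(df, across(where(is.list),
                          ~ vapply(.x, paste, "", collapse = ";")))
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run one pipeline stage from a configuration
#'
#' Binds the modules into reproducible, file-in/file-out stages. `config`
#' is a named list (or path to a YAML file) with stage-specific paths and
#' thresholds; every report embeds the effective parameter set in `#key=value`
#' header lines, and identical config + seed yields byte-identical outputs.
#'
#' Stages: `simulate` (write a synthetic truth set: library, reference,
#' assembly, long reads, truth table), `global` (assembly-vs-reference TE
#' insertion calls), `miv` (long-read minor insertional variants), `tsd`
#' (junction TSD analysis of accepted MIV calls), `illumina`
#' (discordant-pair clusters from a paired-end SAM/BAM), `trap` (binomial
#' trap-model test), `kimura` (intra-family divergence).
#'
#' @param config named list or YAML path. Common keys: `out_dir`, `seed`;
#'   see the stage implementations for the stage-specific keys.
#' @param stage stage name.
#' @return named character vector of the report files written, invisibly.
#' @export
run_pipeline <- function(config, stage) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages <- c("simulate", "global", "miv", "tsd", "illumina", "trap", "kimura")
  if (!stage %in% stages) {
    abort(sprintf("unknown stage '%s' (use one of: %s)", stage,
                  paste(stages, collapse = ", ")))
  }
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  get <- function(key, default = NULL) config[[key]] %||% default
  need <- function(key) {
    v <- config[[key]]
    if (is.null(v)) abort(sprintf("missing config key '%s' for stage %s",
                                  key, stage))
    v
  }
  outfiles <- switch(stage,
    simulate = {
      seed <- as.integer(get("seed", 1))
      lib <- random_te_library(get("n_families", 6), "LTR",
                               tsd_size = get("tsd_size", 4), seed = seed)
      genome <- random_genome(get("genome_len", 1e5), seed = seed + 1)
      sites <- with_seed_if(seed + 2, {
        n <- get("n_fixed", 5) + get("n_minor", 3)
        G <- nchar(genome)
        pos <- sort(sample(seq(3000, G - 3000, by = 10), n))
        while (any(diff(pos) < 6000)) {
          pos <- sort(sample(seq(3000, G - 3000, by = 10), n))
        }
        cls <- sample(c(rep("fixed", get("n_fixed", 5)),
                        rep("minor", get("n_minor", 3))))
        tibble(position = pos, family = sample(lib$name, n, replace = TRUE),
               class = cls,
               frequency = ifelse(cls == "minor",
                                  get("minor_frequency", 0.1), NA_real_))
      })
      sim <- implant_insertions(genome, lib, sites)
      reads <- long_reads(sim, coverage = get("coverage", 30),
                          mean_len = get("mean_len", 8000),
                          profile = ont_error_profile(get("error_rate", 0)),
                          seed = seed + 3)
      f <- stats::setNames(
        file.path(out_dir, c("library.fa", "library.tsv", "reference.fa",
                             "assembly.fa", "reads.fastq", "truth.tsv")),
        c("library_fasta", "library_annot", "reference", "assembly",
          "reads", "truth"))
      write_te_library(lib, f[1], f[2])
      write_fasta(c(chr1 = sim$base_genome), f[3])
      write_fasta(c(chr1 = sim$assembly), f[4])
      write_reads_fastq(reads, f[5])
      write_report_tsv(sim$truth, f[6], params = cfg_params(config))
      f
    },
    global = {
      lib <- load_te_library(need("library_fasta"), need("library_annot"))
      aln <- minimap2_records(need("reference"), need("assembly"),
                              preset = "asm5",
                              sample_id = get("sample_id", "sample"))
      ref <- as.character(Biostrings::readDNAStringSet(need("reference")))
      names(ref) <- sub("\\s.*$", "", names(ref))
      svs <- extract_sv(aln, reference = ref,
                        min_sv_len = get("min_sv_len", 50))
      calls <- classify_sv(svs, lib,
                           min_coverage = get("min_coverage", 0.80),
                           min_identity = get("min_identity", 80))
      f <- stats::setNames(file.path(out_dir, c("global_calls.tsv",
                                                 "global_accepted.bed")),
                           c("calls", "bed"))
      write_report_tsv(calls, f[1], params = cfg_params(config))
      acc <- filter(calls, .data$accepted, .data$kind == "insertion")
      readr::write_tsv(tibble(acc$contig, acc$start, acc$start + 1L,
                              acc$family), f[2], col_names = FALSE,
                       progress = FALSE)
      f
    },
    miv = {
      lib <- load_te_library(need("library_fasta"), need("library_annot"))
      aln <- minimap2_records(need("assembly"), need("reads"),
                              preset = "map-ont",
                              sample_id = get("sample_id", "sample"))
      cands <- candidates_from_reads(aln, min_len = get("min_len", 1000))
      calls <- validate_miv(cands, ltr_subset(lib),
                            min_identity = get("min_identity", 94),
                            min_coverage = get("min_coverage", 0.90),
                            tsd_allowance = get("tsd_allowance", 18))
      f <- stats::setNames(file.path(out_dir, c("miv_calls.tsv",
                                                 "miv_accepted.bed")),
                           c("calls", "bed"))
      write_report_tsv(select(calls, -"sequence"), f[1],
                       params = cfg_params(config))
      acc <- filter(calls, .data$accepted)
      readr::write_tsv(tibble(acc$contig, acc$position, acc$position + 1L,
                              acc$family), f[2], col_names = FALSE,
                       progress = FALSE)
      f
    },
    tsd = {
      lib <- load_te_library(need("library_fasta"), need("library_annot"))
      asm <- as.character(Biostrings::readDNAStringSet(need("assembly")))
      names(asm) <- sub("\\s.*$", "", names(asm))
      aln <- minimap2_records(need("assembly"), need("reads"),
                              preset = "map-ont", sample_id = "sample")
      cands <- candidates_from_reads(aln, min_len = get("min_len", 1000))
      calls <- validate_miv(cands, ltr_subset(lib))
      acc <- filter(calls, .data$accepted)
      seq_by_read <- stats::setNames(aln$seq, aln$read_id)
      flank <- get("flank", 30)
      rows <- list()
      for (i in seq_len(nrow(acc))) {
        kk <- lib$tsd_size[match(acc$family[i], lib$name)]
        if (is.na(kk)) next
        cons <- lib[lib$name == acc$family[i], ]
        ap <- acc$position[i]
        ctg <- asm[[acc$contig[i]]]
        win0 <- max(0, ap - 100)
        empty <- substr0(ctg, win0, min(nchar(ctg), ap + 100 + kk))
        events <- acc$events[[i]]
        for (e in seq_len(nrow(events))) {
          rid <- events$read_id[e]
          res <- tryCatch({
            r <- tsd_for_read(seq_by_read[[rid]], events$qpos[e],
                              events$length[e], cons, kk, empty, ap - win0,
                              flank = flank)
            bind_rows(mutate(r$auto, read_id = rid, family = acc$family[i],
                             contig = acc$contig[i], position = ap),
                      mutate(r$corrected, read_id = rid,
                             family = acc$family[i],
                             contig = acc$contig[i], position = ap))
          }, error = function(err) NULL)
          if (!is.null(res)) rows[[length(rows) + 1L]] <- res
        }
      }
      f <- stats::setNames(file.path(out_dir, "tsd_results.tsv"), "tsd")
      out <- bind_rows(rows)
      if (!nrow(out)) out <- tsd_result("auto", FALSE)[0, ]
      write_report_tsv(out, f[1], params = cfg_params(config))
      f
    },
    illumina = {
      lib <- load_te_library(need("library_fasta"), need("library_annot"))
      rec <- read_pair_records(need("pairs"), get("sample_id", "sample"))
      pairs <- find_discordant(rec, lib$name)
      cl <- cluster_pairs(pairs, max_gap = get("max_gap", 100))
      kept <- filter_clusters(cl, min_reads = get("min_reads", 50))
      f <- stats::setNames(file.path(out_dir, "tei_clusters.tsv"), "clusters")
      write_report_tsv(kept, f[1], params = cfg_params(config))
      f
    },
    trap = {
      calls <- readr::read_tsv(need("calls"), comment = "#",
                               show_col_types = FALSE, progress = FALSE)
      clusters <- readr::read_tsv(need("clusters"), comment = "#",
                                  show_col_types = FALSE, progress = FALSE)
      tt <- trap_test(calls, clusters, genome_length = need("genome_length"),
                      alpha = get("alpha", 0.05))
      f <- stats::setNames(file.path(out_dir, "trap_test.tsv"), "report")
      write_report_tsv(tidy(tt), f[1], params = cfg_params(config))
      f
    },
    kimura = {
      copies <- as.character(Biostrings::readDNAStringSet(need("copies")))
      cons <- as.character(Biostrings::readDNAStringSet(need("consensus")))[1]
      fd <- family_divergence(align_copies(copies, cons))
      f <- stats::setNames(file.path(out_dir, "kimura.tsv"), "report")
      write_report_tsv(
        tibble(mean_d = fd$mean_d, n_used = fd$n_used,
               n_saturated = fd$n_saturated),
        f[1], params = cfg_params(config))
      f
    }
  )
  invisible(outfiles)
}
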