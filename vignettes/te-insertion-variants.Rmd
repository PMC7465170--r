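---
title: "Detecting TE insertion variants from long and short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE insertion variants from long and short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable elements (TEs) reshape genomes on the timescale of a few
generations. Two kinds of insertion variant matter when comparing strains or
following a transposition burst:

* **Global variants** — insertions frequent enough in the sequenced
  population to be incorporated into a de novo assembly. They are visible as
  large insertion operations when the assembly is aligned back to a
  reference genome.
* **Minor insertional variants (MIVs)** — insertions segregating at low
  frequency (down to a single individual in a pool). They never make it
  into the consensus assembly; the only evidence is one or a few long reads
  that carry the insertion when re-mapped to the sample's *own* assembly.

`tevariant` implements both detectors, plus the downstream analyses that
make the calls interpretable: target-site-duplication (TSD) validation of
single-read LTR insertions, a discordant-pair caller for paired-end short
reads, Kimura-2-parameter (K2P) intra-family divergence, and a binomial
test of piRNA-cluster insertion enrichment ("trap model"). A synthetic-data
module generates genomes, insertions and reads with known truth so every
stage is testable end to end without external data.

## Global variants

`extract_sv()` walks alignment CIGARs and emits one record per insertion or
deletion operation of at least `min_sv_len` nt (default 50 nt, the usual SV
floor for assembly comparisons; the value is configurable because it is a
convention, not a biological constant). Coordinates are 0-based half-open
on the reference; an insertion is a point with the inserted sequence
attached, a deletion carries the removed reference slice.

`classify_sv()` aligns each SV sequence against every entry of a TE
consensus library (Smith–Waterman-style local alignment, both strands) and
reports the best hit — highest score, ties broken by consensus coverage and
then family name so results are deterministic. A call is *accepted* when it
covers **more than** 80% of the consensus at **more than** 80% identity
(strict inequalities; identity counts gap columns in its denominator,
matching BLAST-style identity). Setting both thresholds to 0 gives an
unfiltered mode in which the best hit is always reported, useful when
screening divergent or fragmented copies.

## Minor insertional variants

`candidates_from_reads()` mines CIGAR insertion operations **longer than**
1000 nt from long-read-versus-assembly alignments. Per-read events on the
same contig are merged into one candidate when their positions lie within
100 nt and their lengths agree to within a ratio of 0.8; the longest event
contributes the candidate sequence and position, and the merged reads the
support count. Support of 1 is meaningful — single-read sensitivity is the
point of the method — so no support filter is applied here.

`validate_miv()` assigns each candidate its best LTR family and accepts it
when three conditions hold:

| condition | rule | rationale |
|---|---|---|
| identity | > 94% | separates true copies from old, diverged ones at ONT-consensus accuracy |
| consensus coverage | ≥ 90% | requires a near-full-length element |
| length excess | ≤ 18 nt | an insertion may exceed its consensus by at most the largest TSD reported for LTR elements |

The identity bound is strict and the coverage bound inclusive; the
acceptance rule is exposed directly as `miv_accept()` so the boundary
behaviour is testable in isolation. Acceptance is monotone: raising a
threshold can only shrink the accepted set.

## TSD detection and error correction

An LTR integration duplicates its `k`-nt genomic target (here `k` is
4–5 nt, family-specific), leaving `[target][TE][target]` at the locus.
`detect_tsd_auto()` extracts 30-nt flanks on both sides of the TE span
within a read (located with `te_span_in_read()`, anchored at the read's own
insertion event so other copies of the family elsewhere in a long read
cannot capture the span) and looks for an *exact* `k`-mer shared between
the junction-proximal ends of the two flanks, allowing up to 5 nt of
breakpoint jitter. Exact matching on such short motifs controls false
positives; the jitter absorbs alignment imprecision at the junctions.

Single long reads carry enough sequencing error that a genuine TSD often
fails exact detection. When the assembly retains the *empty* allele of the
target site, `detect_tsd_corrected()` aligns each read flank to its
genomic counterpart (global minimum-edit alignment) and replaces read
errors with genomic bases before re-running the automatic search. Two
gates prevent the correction from manufacturing a TSD out of genomic
sequence alone:

1. each flank must align to its genomic counterpart within
   `max_flank_dist` edits (default `ceiling(flank/3)` = 10 for 30-nt
   flanks, about three times the error expected at a few percent per-base
   error);
2. the read bases aligned to the target `k`-mer on each side may differ
   from it by at most `max_tsd_edits` (default 1) — the junction-defining
   copies must remain supported by the read itself. This is the strictness
   knob: 0 demands error-free TSD copies, larger values approach
   uncorrected trust in the genomic sequence.

Flanks unrelated to the empty site fail gate 1; a corrupted TSD copy fails
gate 2. If the automatic search already succeeds on the raw flanks, the
corrected mode returns that result unchanged, so correction can never
destroy a clean junction. Because a noisy alignment can also misplace the
insertion point by a few bases, the empty-site coordinate is searched
within ±`site_search` nt (default 5, matching the jitter) for the offset
minimising the total flank edit distance.

`extract_tsm()` returns the target site motif — the TSD extended by exactly
one genomic nt on each side, giving the familiar 6-nt motif for a 4-nt
TSD — and `build_pfm()`/`information_content()` provide the count matrix
and per-position bits used for sequence logos.

## Short-read discordant pairs

`find_discordant()` keeps read pairs in which exactly one mate maps to the
genome, the other to a TE consensus, and no concordant genomic placement
exists. `cluster_pairs()` chains genome-mate positions per (contig, family)
with single linkage and an **inclusive** 100-nt gap; the cluster position
is the rounded mean of its members (half-up rounding, for platform
determinism) and its strength the read count. Clusters are per-family so
that downstream per-family insertion counts are direct. `filter_clusters()`
retains clusters with at least 50 supporting reads (inclusive) — a
pool-sequencing convention that suppresses PCR artefacts.

## Statistics

**K2P divergence.** `pairwise_PQ()` classifies aligned columns into
transitions and transversions, ignoring gap and `N` columns;
`k2p_distance()` evaluates `d = -1/2·ln((1-2P-Q)·sqrt(1-2Q))` and refuses
saturated inputs. `family_divergence()` averages per-copy copy-versus-
consensus distances (saturated copies are excluded and counted); the mean
proxies the age of a family's recent transposition wave.

**Trap model.** If piRNA clusters trap transposing elements, new
insertions should be enriched inside them. `trap_test()` takes the
insertion positions and the cluster intervals, merges overlapping clusters,
sets `p` to the merged fraction of the genome, counts in-cluster insertions
with half-open interval membership, and evaluates the one-tailed exact
binomial upper tail. `min_significant()` reports the smallest observed
count that would reject uniform insertion at level `alpha`, under a strict
`p < alpha` rejection rule; the tail itself is computed exactly
(`pbinom`), never by normal approximation.

## piRNA cluster utilities

`locate_cluster()` places a cluster in a new assembly from its flanking
sequences: with two flanks the interval runs between the inner hit ends
(orientation-agnostic); with one flank plus an annotated length the
interval extends downstream of the flank's inner end — the choice of side
is a convention, stated here because the flank annotation does not encode
it. `filter_pirna_reads()` keeps reads strictly longer than 23 nt that do
not match any known other small RNA end-to-end within 2 mismatches;
`unique_map_counts()` emulates best-stratum unique mapping (`-v 2 -m 1`
behaviour); `window_counts()` tiles genome-anchored 1-kb windows, and
`producers()` applies the strict >500 raw-read rule before any
normalisation (`normalize_by_mirna()` scales reported abundances by the
library's miRNA content only).

## The synthetic-data generator

`random_genome()` draws i.i.d. bases at 42% GC (fly-like).
`implant_insertions()` duplicates the `k`-nt target at each site so the
locus reads `[target][TE][target]`; **fixed** insertions are written into
the returned assembly while **minor** insertions are recorded in the truth
table and applied per read template with their population frequency — a
10% minor variant appears in ~10% of the reads spanning its site and never
in the assembly, exactly the situation that distinguishes MIVs from global
variants. `long_reads()` draws gamma-distributed lengths (shape 2, heavy
enough in the tail to span full LTR elements), uniform starts, random
strands and an ONT-like error profile (40% substitutions / 30% insertions /
30% deletions of the total rate, via `ont_error_profile()`).
`paired_reads()` draws fragments and annotates each mate against the truth,
so the discordant-pair caller can be tested without a short-read mapper.

The package's standard validation conditions (`run_synthetic_benchmark()`)
are a 100-kb genome, a 6-family LTR library of 1.5–2.5-kb consensus
sequences with 4-nt TSDs, 5 fixed + 3 minor insertions (10% frequency,
sites ≥6 kb apart so one read sees at most one site), and 30× reads of
mean length 8 kb. These sizes keep a full run to a couple of minutes on one
CPU while leaving every stage non-trivially exercised; assembly-scale
contiguity, repeat-induced mis-assembly and basecaller-specific error
contexts are deliberately *not* modelled, so passing the synthetic
benchmark demonstrates algorithmic correctness, not robustness to every
artefact of real libraries. Mapping inside the benchmark and the pipeline
stages is delegated to minimap2 (presets `asm5` and `map-ont`), the mapper
this kind of data is normally processed with.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally and converted at
  I/O boundaries (SAM is 1-based).
* Local alignment uses BLASTN-like scoring (+2/−3, gap −5/−2·L),
  configurable via `align_scoring()`; `N` scores as a mismatch against
  everything including itself. Sequences outside `{A,C,G,T,N}` are
  rejected at entry rather than silently coerced.
* All best-hit and strand ties are broken deterministically (score, then
  coverage/target span, then leftmost start, then `+` strand, then name).
* Zero comparable columns (K2P), empty libraries, saturated distances,
  zero-length targets and flankless junctions raise errors instead of
  returning sentinel values.
* Every report written by `run_pipeline()` embeds the effective parameter
  set and package version in `#key=value` header lines; identical
  configuration and seed give byte-identical outputs.

## Limitations

* Only CIGAR insertion operations are mined for MIVs; split-read and
  soft-clip insertion signatures (and inversions, translocations) are out
  of scope, as is non-LTR MIV calling.
* The discordant-pair caller does not estimate insertion frequency within
  pools, and applies no mapping-quality floor by default.
* The TSD corrector requires the empty allele to be present in the
  assembly; insertions fixed in the sample cannot be corrected this way.
* The identity filter near its 94% boundary interacts with raw-read error:
  at ~5% per-base error a single-read candidate sits close to the
  threshold, so MIV recall on noisy reads is conservative by construction.
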