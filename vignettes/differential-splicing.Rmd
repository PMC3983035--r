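---
title: "Junction-based differential splicing and positional motif maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-based differential splicing and positional motif maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the tunable parameters and the design
choices behind `dasmap`. The package analyses a minimal two-condition
(control vs regulator-knockdown) single-end RNA-seq design with one library
per condition — the setting in which differential splicing is assessed
event-by-event with Fisher's exact test rather than with replicate-aware
models.

## Coordinates and junction library

All coordinates are 0-based half-open internally; GTF input/output converts
at the boundary (1-based closed). This removes every ±1 ambiguity from
junction anchors: a junction is the pair (donor, acceptor) where the donor
is the transcription-3′ coordinate of the upstream exon and the acceptor the
transcription-5′ coordinate of the downstream exon.

The library joins **every** exon of a gene to **all** exons downstream of it
in transcription direction, pooling exons over all transcripts and
deduplicating by (donor, acceptor) within the gene (identical coordinates in
two different genes stay two entries). Each side of a junction sequence
carries `flank = read_len − min_overhang` nt of exonic sequence (44/69 nt
for 50/75-nt reads at the default `min_overhang = 6`): a read aligned
anywhere on the junction sequence then necessarily overhangs the junction
point by at least `min_overhang` nt on the far side, which is what makes the
flank length the operative constant of the whole library. Exons shorter than
the flank truncate it (the entry is flagged) rather than dropping the
junction — dropping would silently remove short-exon events.

## Read assignment

Reads are assigned by Hamming distance (substitutions only, no indels, the
error model of the simulator) with `max_mismatches = 3`. Candidate
placements are enumerated with a pigeonhole seed index: a read split into
`max_mismatches + 1` disjoint segments must match at least one segment
exactly, so an exact k-mer index over both genome strands and the
sense-oriented junction sequences finds every placement within the mismatch
budget; candidates are verified base by base. A read is **unique** iff
exactly one placement attains the minimum mismatch count; everything else
(ambiguous, unplaced) is dropped and tallied. This minimum-mismatch
uniqueness rule is a deliberate, testable contract — short-read aligners'
notions of "ambiguous" depend on reporting modes, so the package pins down
one exact definition and validates it against a brute-force scan.

Junction placements must genuinely span the junction (≥ 1 nt each side);
placements lying entirely inside one flank duplicate a genome placement and
are discarded before uniqueness is decided. Junction *counting* then applies
the two reporting rules: a read contributes only with a two-sided overhang
of at least `min_overhang` nt, and a junction is reported only when covered
by at least `min_independent = 2` *independent* reads, defined as distinct
alignment start offsets. The distinct-offset definition is our choice (the
notion of "independent" is otherwise underspecified); it guards against
duplicate read stacks supporting a junction on their own.

## Event calling and PSI

Events are found by pairwise transcript comparison within a gene: shared
exons act as anchors and each non-shared block between anchors is
classified — one extra internal exon (SE), a two-exon block merged into one
(IR), a single exon differing at its donor/acceptor edge (A5SS/A3SS,
strand-aware), two non-overlapping alternatives between anchors (MXE) or at
a transcript end (AFE/ALE). Duplicate events found in several transcript
pairs are merged under a canonical identity (unordered pair of defining
intervals), so enumeration is invariant to transcript listing order.

Inclusion labels are fixed per type: SE — the cassette-containing isoform;
IR — retention; A5SS/A3SS — the longer (more exonic) variant; MXE — the
genomically upstream exon; AFE/ALE — the first-listed variant. For MXE and
AFE/ALE the label is a bookkeeping convention; direction calls downstream
depend only on the sign of ΔPSI, so the convention is immaterial to the
biology reported.

Read evidence is junction-only: SE inclusion sums its two flanking
junctions, exclusion the skip junction; exon-body reads are never counted
(they cannot discriminate isoforms without length modelling). IR retention
— which has no inclusion junction — is evidenced by genome-aligned reads
spanning either exon–intron boundary with the same ≥ 6 nt two-sided rule,
and the same ≥ 2-distinct-offset independence rule applied per boundary.
PSI normalizes by junction multiplicity,

    psi = (inc / n_inc) / (inc / n_inc + exc / n_exc),

compensating the 2-vs-1 junction asymmetry of SE and MXE; it is undefined
(and the event untestable) when both terms are zero.

## Statistics

Each event's 2×2 table (inclusion/exclusion × control/treated) gets a
two-sided Fisher exact p: the sum of hypergeometric probabilities of all
tables with the observed margins whose probability is at most that of the
observed table (relative tolerance 1e−7, the standard tie guard).
Benjamini–Hochberg is applied once across all testable events of all types;
tables with an all-zero row or column are excluded *before* correction
rather than assigned p = 1, so they do not dilute the multiplicity burden.
With treated = knockdown, significant events with ΔPSI < 0 are
regulator-activated and ΔPSI > 0 regulator-repressed; no ΔPSI floor is
imposed beyond the q < 0.05 criterion. The expression filter uses
RPKM = 10⁹·count/(total·length) computed on uniquely mapped reads, passing
genes whose larger-sample RPKM is ≥ 0.5 with a strict > 2-fold change
(the larger-sample reading resolves an ambiguity in which sample must clear
the floor).

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture: each
requested event becomes one gene with exactly two isoforms differing only by
that event, laid out on one contig with alternating strands (so every
strand-sensitive code path is exercised by default). Defaults: 150-nt exons
(≥ 2·(read_len−6), so junction flanks never truncate), 250-nt introns
(≥ 80 nt, so the RNA-map upstream window never collides with the opposite
splice site), uniform-random background sequence, uniform read starts,
i.i.d. substitution errors, Phred33 FASTQ with constant quality.

PSI is defined as the **molar** fraction of transcripts carrying the
inclusion isoform. Under uniform sequencing, read counts per isoform are
proportional to abundance × length, so a read originates from the inclusion
isoform with probability `psi·L_inc / (psi·L_inc + (1−psi)·L_exc)`. This
length weighting matters: with length-blind isoform sampling the
junction-count PSI estimator would be biased by up to ~0.1 simply because
the two isoforms of an event differ in mRNA length by construction, whereas
under the molar model the estimator's residual bias (edge effects of order
`L/(L−read_len+1)`) stays below ~0.02 and the acceptance-level accuracy
target (mean |error| < 0.03 at ≥ 200 reads/event) is attainable.

Motifs are planted in DNA space on the sense strand (ACUAAU ↔ ACTAAT,
reverse-complemented for minus-strand genes) at fixed offsets from the
cassette exon's splice sites, overwriting the background. What the generator
does **not** emulate: positional/GC coverage bias, indels, paired ends, PCR
duplicates, overlapping genes, nested or complex event graphs, and
expression confounding beyond a global depth. Passing tests therefore
demonstrate correctness of the pipeline's logic and calibration of its
statistics under clean assumptions — not robustness to real-library
artifacts.

## RNA map

The profile frame is: last U nt of the upstream exon, the upstream intron's
first ⌊I/2⌋ nt (anchored at its 5′ss) and last ⌈I/2⌉ nt (anchored at the
3′ss), the cassette exon length-normalized to E bins, the downstream intron
likewise, and the first U nt of the downstream exon; defaults U = 50,
I = 250, E = 50 (unstated in the literature figure the layout follows, so
configurable). Introns shorter than I contribute what they have, split in
half to avoid double counting; uncovered positions are excluded from
averaging rather than zero-filled. Matching is exact (the literal consensus
ACUAA(U/C)), overlapping matches allowed, on the pre-mRNA sense strand
only; the UAAU/UAAC half sites are available as a separate track and are
never summed into the core curve. A centered sliding window (default 20 nt)
smooths the intron and exon-flank tracks for display; all tests run on the
unsmoothed profile.

The control band resamples `set_size` events from the control pool without
replacement and takes empirical quantiles of the per-position means —
empirical rather than normal-theory because per-position counts are small,
discrete and zero-inflated. Extreme levels (such as 99.9999%) are honest
only with enormous resample counts; when `n_resamples < 2/(1−level)` the
function warns and reports the achievable level `1 − 2/n_resamples` instead
of fabricating quantiles beyond its resolution. The branchpoint-window test
compares mean motif counts in [−40, −1] nt upstream of the 3′ss between the
regulated set and the control pool, with an add-one-corrected permutation p
from size-matched control resamples (so the smallest reportable p is
1/(n_perm+1)); a zero control density is reported as an infinite ratio with
the permutation p still computed. The default control-pool definition —
tested events with q ≥ 0.5 — is a flag-overridable choice; alternatives
(expression-matched pools) are out of scope.

## Problem sizes and numerical choices

The test suite validates the aligner against an exhaustive Hamming scan on
a ~7-kb genome with 2,000 reads; power/FDR of the event test on 50
replicates of 120 events (100 null, 20 at ΔPSI = 0.4, ~200 reads each); PSI
accuracy end-to-end at ~60,000 reads over 8 events; and RNA-map recovery
with 20 activated / 20 repressed / 60 control cassette exons (bands at the
95% level with 1,000 resamples). These sizes were chosen so the whole suite
runs on a laptop in a few minutes while keeping every Monte-Carlo margin
well away from its threshold; all randomness is seeded, and rerunning any
stage with the same seed is bitwise-identical.

## Known limitations

One library per condition means no within-condition variance estimate: the
Fisher test treats reads as independent draws, so biological variability is
out of scope by design (replicate-aware GLMs would be the extension). The
aligner is a toy-genome instrument — exact Hamming search with a k-mer hash
— and is not meant to scale to mammalian genomes. Event calling handles the
seven canonical local differences; complex blocks (three or more differing
exons between anchors) are deliberately skipped. AFE/ALE calls based on
terminal-exon differences cannot distinguish alternative promoters or
polyadenylation from splicing proper without additional data.
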