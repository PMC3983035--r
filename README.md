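# dasmap

Differential alternative splicing from junction reads, with positional
RNA-binding-motif maps.

## The problem

Splicing regulators such as the STAR-family protein QKI reshape the
transcriptome by switching individual exons on or off. A standard way to
characterize such a regulator from bulk RNA-seq is a knockdown experiment
with one library per condition: count the reads supporting the inclusion and
exclusion isoform of every annotated alternative-splicing event, test each
event for a change between conditions, and then ask *where* the regulator's
sequence motif sits relative to the exons it activates versus the exons it
represses (the "RNA map"). `dasmap` implements that workflow end to end as a
tested R package, together with a synthetic-data generator that plants known
events, PSI values and motifs so every stage can be validated against ground
truth.

## The method

1. **Junction library.** From a GTF, every exon of a gene is joined to every
   exon downstream of it (in transcription direction, pooled over all
   transcripts). Each junction carries `read_len − overhang` nt of exonic
   sequence per side — 44 nt for 50-nt reads and 69 nt for 75-nt reads at
   the default 6-nt minimum overhang — so any read alignment must extend at
   least 6 nt across the junction point.
2. **Read assignment.** Reads are placed on both genome strands and on the
   sense-oriented junction sequences by Hamming distance, allowing up to 3
   mismatches. A read is kept only if exactly one placement attains the
   minimum mismatch count; ambiguous reads are discarded. A junction is
   reported only when covered by ≥ 2 *independent* reads (distinct start
   offsets).
3. **Event calling.** Pairwise transcript comparison yields seven event
   types — cassette exon (SE), retained intron (IR), alternative 5′/3′
   splice site (A5SS/A3SS), mutually exclusive exons (MXE), alternative
   first/last exon (AFE/ALE) — each with inclusion- and exclusion-evidence
   junction sets (IR retention is evidenced by exon–intron boundary-spanning
   reads).
4. **Statistics.** Per event, a two-sided Fisher's exact test on the 2×2
   table of inclusion/exclusion counts in control vs treated, with
   Benjamini–Hochberg correction across all testable events (significant at
   q < 0.05). PSI is the junction-normalized inclusion fraction
   `(inc/n_inc) / (inc/n_inc + exc/n_exc)`; since treated is a knockdown,
   ΔPSI < 0 labels an event regulator-**activated** and ΔPSI > 0
   regulator-**repressed**. An RPKM filter (`10^9·count/(total·length)`,
   ≥ 0.5, fold > 2) flags expression-level changes.
5. **RNA map.** Exact occurrences of the QKI consensus ACUAA(U/C) are
   profiled position-wise around activated, repressed and control cassette
   exons (anchored exon flanks, intron halves anchored at the splice sites,
   length-normalized exon bins), with a confidence band from resampling the
   control pool and a permutation test for enrichment in the branchpoint
   window 40 nt upstream of the 3′ splice site.

## Worked example

The `analysis/` scripts run the whole study on simulated data (60 cassette
exons — 15 activated, 15 repressed, 30 controls — plus two events of each
other type; ~21,000 50-nt reads per condition at 0.2% error):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_junction_library.R
Rscript analysis/03_align_reads.R
Rscript analysis/04_call_events.R
Rscript analysis/05_differential_splicing.R
Rscript analysis/06_rna_map.R
```

which prints, stage by stage:

```
simulated 72 genes (72 AS events, 34 planted changes) on a 88,832-nt genome
junction library: 214 junctions over 72 genes (flank 44 nt/side, 0 truncated)
control: 21372 reads -> 21182 unique (99.1%), 0 ambiguous, 190 unaligned; 206 junctions reported
events called: A3SS=2 A5SS=2 AFE=2 ALE=2 IR=2 MXE=2 SE=60
34 events in 34 genes significant (BH q < 0.05; 72 tested)
ground truth: sensitivity 1.000 (34/34 planted), 0 false discoveries (FDP 0.000)
repressed-set profile peak: region intron_up_3p, offset -25 (mean 1.00 motifs/exon)
branchpoint-window enrichment: density ratio Inf (repressed 1.00 vs control 0.000 motifs/exon), permutation p = 0.001
```

Every planted splicing change is recovered with no false discoveries; the
motif profile of the repressed set peaks exactly where the generator planted
the consensus (25 nt upstream of the 3′ splice site, the branchpoint
region), and the upstream-window enrichment is as significant as 1,000
permutations can resolve. The same stages are available as one call,
`run_pipeline(config, dir)`, which also writes a manifest with checksums and
seeds; `summarize_run(dir)` reports significant events per type, direction
breakdown and ground-truth recovery.

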