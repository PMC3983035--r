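#!/usr/bin/env Rscript
# Stage 2 — build the splice-junction library: every exon joined to all
# downstream exons of the same gene, with 44 nt of exonic sequence per side
# (50-nt reads, 6-nt minimum overhang), exported as FASTA plus a TSV index.

library(dasmap)

run_dir <- "results/analysis/run"
genome <- read_fasta(file.path(run_dir, "genome.fa"))
genes <- read_gtf(file.path(run_dir, "annotation.gtf"))

lib <- build_junction_library(genes, genome, read_len = 50L, min_overhang = 6L)
write_junction_library(lib, file.path(run_dir, "junctions.fa"),
                       file.path(run_dir, "junctions.tsv"))

cat(sprintf("junction library: %d junctions over %d genes (flank %d nt/side, %d truncated)\n",
            nrow(lib), length(unique(lib$gene_id)), lib$flank_len[1],
            sum(lib$truncated)))
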