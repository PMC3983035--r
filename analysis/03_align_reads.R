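#!/usr/bin/env Rscript
# Stage 3 — assign reads to genome and junction targets allowing up to three
# mismatches, drop ambiguously placed reads, and count junction support
# (independent = distinct start offsets; junctions reported at >= 2).

library(dasmap)

run_dir <- "results/analysis/run"
genome <- read_fasta(file.path(run_dir, "genome.fa"))
genes <- read_gtf(file.path(run_dir, "annotation.gtf"))
lib_idx <- read.table(file.path(run_dir, "junctions.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
lib_seq <- read_fasta(file.path(run_dir, "junctions.fa"))
lib_idx$seq <- unname(unclass(lib_seq)[lib_idx$junction_id])
class(lib_idx) <- c("junction_library", "data.frame")

index <- build_align_index(genome, lib_idx, read_len = 50L, max_mismatches = 3L)
for (cond in c("control", "treated")) {
  reads <- read_fastq(file.path(run_dir, paste0(cond, ".fastq")))
  aln <- align_reads(reads, index = index, max_mismatches = 3L)
  cnt <- count_junctions(aln, min_overhang = 6L, min_independent = 2L)
  write.table(aln, file.path(run_dir, paste0("alignments_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnt, file.path(run_dir, paste0("junction_counts_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- attr(aln, "summary")
  cat(sprintf("%s: %d reads -> %d unique (%.1f%%), %d ambiguous, %d unaligned; %d junctions reported\n",
              cond, s["total"], s["unique"], 100 * s["unique"] / s["total"],
              s["ambiguous"], s["unaligned"], sum(cnt$reported)))
}
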