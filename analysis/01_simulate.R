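#!/usr/bin/env Rscript
# Stage 1 — simulate the study: a two-condition (control vs regulator
# knockdown) single-end RNA-seq experiment over genes carrying known
# alternative-splicing events. Cassette exons are split into
# regulator-activated (PSI drops on knockdown), regulator-repressed (PSI
# rises) and unregulated controls; ACUAAU consensus motifs are planted 25 nt
# upstream of the 3' splice site of repressed exons and 30 nt into the
# downstream intron of activated exons, mirroring a position-dependent
# splicing regulator.

library(dasmap)

dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)
run_dir <- "results/analysis/run"

n_act <- 15; n_rep <- 15; n_ctl <- 30
n_se <- n_act + n_rep + n_ctl
psi <- data.frame(
  event_id = sprintf("SE_%d", seq_len(n_se)),
  psi_control = c(rep(0.8, n_act), rep(0.3, n_rep), rep(0.5, n_ctl)),
  psi_treated = c(rep(0.3, n_act), rep(0.8, n_rep), rep(0.5, n_ctl)))
# the non-SE events: one changing and one null per type
other <- data.frame(
  event_id = c("IR_1", "A5SS_1", "A3SS_1", "MXE_1", "AFE_1", "ALE_1"),
  psi_control = c(0.7, 0.6, 0.5, 0.4, 0.5, 0.6),
  psi_treated = c(0.2, 0.2, 0.5, 0.8, 0.5, 0.1))
plan <- data.frame(label = c("repressed", "activated"),
                   anchor = c("3ss", "5ss"), offset = c(-25L, 30L),
                   motif = "ACUAAU", stringsAsFactors = FALSE)

cfg <- sim_config(seed = 42, read_len = 50L,
                  events_per_type = c(SE = n_se, IR = 2, A5SS = 2, A3SS = 2,
                                      MXE = 2, AFE = 2, ALE = 2),
                  psi = rbind(psi, other), depth = 800, error_rate = 0.002,
                  motif_plan = plan)

sim <- simulate_annotation(cfg)
dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
write_fasta(sim$genome, file.path(run_dir, "genome.fa"))
write_gtf(sim$genes, file.path(run_dir, "annotation.gtf"))
write.table(sim$truth$events, file.path(run_dir, "truth_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$motifs, file.path(run_dir, "truth_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
rd <- simulate_reads(sim, run_dir)

cat(sprintf("simulated %d genes (%d AS events, %d planted changes) on a %s-nt genome\n",
            length(sim$genes), nrow(sim$truth$events),
            sum(sim$truth$events$psi_control != sim$truth$events$psi_treated),
            format(nchar(sim$genome[[1]]), big.mark = ",")))
cat(sprintf("reads: %d control, %d treated (50 nt, error rate %.3f)\n",
            sum(rd$origins$condition == "control"),
            sum(rd$origins$condition == "treated"), cfg$error_rate))
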