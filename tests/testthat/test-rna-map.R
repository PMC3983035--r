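# shared fixture: SE genes with activated / repressed / control labels and
# consensus motifs planted upstream (repressed) and downstream (activated)
rna_map_sim <- function(seed = 41, n_act = 8, n_rep = 8, n_ctl = 24) {
  n <- n_act + n_rep + n_ctl
  psi <- data.frame(
    event_id = sprintf("SE_%d", seq_len(n)),
    psi_control = c(rep(0.8, n_act), rep(0.3, n_rep), rep(0.5, n_ctl)),
    psi_treated = c(rep(0.3, n_act), rep(0.8, n_rep), rep(0.5, n_ctl)))
  plan <- data.frame(label = c("repressed", "activated"),
                     anchor = c("3ss", "5ss"), offset = c(-25L, 30L),
                     motif = "ACUAAU", stringsAsFactors = FALSE)
  cfg <- sim_config(seed = seed, events_per_type = c(SE = n), psi = psi,
                    motif_plan = plan)
  simulate_annotation(cfg)
}

truth_sets <- function(sim) {
  ev <- sim$truth$events
  split(ev, ev$label)[c("activated", "repressed", "control")]
}

test_that("motif scanning finds exact overlapping consensus matches in RNA
           or DNA space", {
  expect_length(scan_motif("ACUUAU"), 0)   # a plain branchpoint, not a site
  expect_equal(scan_motif("ACUAAU"), 1L)   # the consensus itself
  expect_equal(scan_motif("ACUAACACUAAU"), c(1L, 7L))
  expect_equal(scan_motif("ACTAATACTAAC"), c(1L, 7L))  # DNA-space input
  expect_equal(scan_motif("acuaau"), 1L)
  expect_equal(scan_motif("UAAUAAC", c("UAAU", "UAAC")), c(1L, 4L))
  expect_length(scan_motif("ACG"), 0)      # shorter than the motif
})

test_that("region extraction is strand-symmetric", {
  sim <- rna_map_sim(seed = 43, n_act = 2, n_rep = 2, n_ctl = 4)
  ev <- sim$truth$events
  # genes alternate strands by construction; mirror the genome and flip
  # strand labels: element sequences must be unchanged
  g <- sim$genome
  mirrored <- dasmap:::validate_genome(setNames(revcomp(unclass(g)), names(g)))
  N <- nchar(g[[1]])
  for (i in seq_len(nrow(ev))) {
    el <- dasmap:::se_element_seqs(ev[i, ], sim$genes, sim$genome)
    gm <- sim$genes[[ev$gene_id[i]]]
    gm$strand <- if (gm$strand == "+") "-" else "+"
    gm$transcripts <- lapply(gm$transcripts, function(ex) {
      out <- data.frame(start = N - ex$end, end = N - ex$start)
      out[order(out$start), ]
    })
    ev2 <- ev[i, ]
    ev2$alt_start <- N - ev$alt_end[i]; ev2$alt_end <- N - ev$alt_start[i]
    genes2 <- sim$genes; genes2[[ev$gene_id[i]]] <- gm
    el2 <- dasmap:::se_element_seqs(ev2, genes2, mirrored)
    expect_equal(el2, el)
  }
})

test_that("planted upstream motifs produce a peak at -25..-20 from the 3'ss
           and nowhere upstream for downstream-planted sets", {
  sim <- rna_map_sim()
  sets <- truth_sets(sim)
  prof <- build_motif_map(sets, sim$genes, sim$genome)
  rp <- prof[prof$set == "repressed" & prof$region == "intron_up_3p", ]
  peak_off <- rp$offset[which.max(rp$mean)]
  expect_true(peak_off >= -25 && peak_off <= -20)
  expect_gt(max(rp$mean), 0.9)    # every repressed exon carries one motif
  ap <- prof[prof$set == "activated", ]
  dn5 <- ap[ap$region == "intron_dn_5p", ]
  expect_true(dn5$offset[which.max(dn5$mean)] %in% 31:36)
  up3 <- ap[ap$region == "intron_up_3p", ]
  expect_lt(max(up3$mean), 0.5)   # no upstream peak for the activated set
  # conservation: profile totals equal per-event scan totals within coverage
  mm <- dasmap:::event_motif_matrix(sets$repressed, sim$genes, sim$genome)
  expect_equal(sum(colSums(mm$hits)), sum(mm$hits))
  expect_equal(nrow(mm$hits), nrow(sets$repressed))
})

test_that("control profiles are flat and the confidence band is deterministic
           under a seed", {
  sim <- rna_map_sim()
  sets <- truth_sets(sim)
  prof <- build_motif_map(sets["control"], sim$genes, sim$genome)
  ctl <- prof[prof$region != "cassette", ]
  # uniform background: no position sticks out beyond small-sample noise
  expect_lt(max(ctl$mean, na.rm = TRUE), 0.25)
  b1 <- control_confidence_band(sets$control, sim$genes, sim$genome,
                                set_size = 8, n_resamples = 200,
                                level = 0.95, seed = 5)
  b2 <- control_confidence_band(sets$control, sim$genes, sim$genome,
                                set_size = 8, n_resamples = 200,
                                level = 0.95, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$band_high >= b1$band_low, na.rm = TRUE))
  # level 0 collapses the band onto the resampled median
  b0 <- control_confidence_band(sets$control, sim$genes, sim$genome,
                                set_size = 8, n_resamples = 200,
                                level = 0, seed = 5)
  expect_equal(b0$band_low, b0$band_high)
  # unachievable extreme level falls back with a warning
  expect_warning(
    control_confidence_band(sets$control, sim$genes, sim$genome,
                            set_size = 8, n_resamples = 100,
                            level = 0.999999, seed = 5),
    "achievable")
  expect_error(
    control_confidence_band(sets$control, sim$genes, sim$genome,
                            set_size = 1000, n_resamples = 10, seed = 1,
                            level = 0.95),
    "smaller than set_size")
})

test_that("upstream-window enrichment is null for control exons and
           saturated for planted repressed exons", {
  sim <- rna_map_sim(seed = 47, n_act = 2, n_rep = 8, n_ctl = 150)
  sets <- truth_sets(sim)
  # identity: comparing the pool to itself forces a unit density ratio
  null <- upstream_window_enrichment(sets$control, sets$control,
                                     sim$genes, sim$genome,
                                     n_perm = 400, seed = 6)
  expect_gt(null$mean_control, 0)         # background density present
  expect_equal(null$density_ratio, 1, tolerance = 1e-9)
  expect_gt(null$p, 0.3)
  # a null subset of the pool must not look enriched
  sub <- sets$control[seq_len(40), ]
  null2 <- upstream_window_enrichment(sub, sets$control,
                                      sim$genes, sim$genome,
                                      n_perm = 400, seed = 6)
  expect_gt(null2$p, 0.05)
  enr <- upstream_window_enrichment(sets$repressed, sets$control,
                                    sim$genes, sim$genome,
                                    n_perm = 400, seed = 6)
  expect_gte(enr$mean_repressed, 1)       # one planted motif per exon
  expect_lte(enr$p, 1.5 / 400)
})
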