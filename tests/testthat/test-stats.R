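test_that("Fisher two-sided p matches closed forms and the enumeration
           oracle", {
  # extreme table: only two tables this improbable among fixed margins
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # perfectly balanced table carries no signal
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(12, 3, 4, 11),
               fisher_enum_oracle(12, 3, 4, 11), tolerance = 1e-9)
  expect_error(fisher_exact_two_sided(0, 0, 3, 4), "untestable")
  expect_error(fisher_exact_two_sided(2, 0, 3, 0), "untestable")
})

test_that("Fisher p agrees with stats::fisher.test and is invariant under
           simultaneous row/column swaps", {
  set.seed(71)
  for (i in 1:200) {
    t <- rpois(4, 8)
    if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
        (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
    p <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-7)
    # swap both rows and both columns
    expect_equal(fisher_exact_two_sided(t[4], t[3], t[2], t[1]), p,
                 tolerance = 1e-12)
  }
  # tables proportional across conditions are maximally null
  expect_equal(fisher_exact_two_sided(2, 3, 4, 6), 1)
  expect_equal(fisher_exact_two_sided(10, 5, 20, 10), 1)
})

test_that("BH adjustment matches the textbook step-up and its monotonicity
           properties", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(72)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p))  # rank-monotone
  }
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.1, 0)), "in \\(0, 1\\]")
})

test_that("BH thresholding equals the classical step-up rejection set", {
  set.seed(73)
  alpha <- 0.05
  for (i in 1:20) {
    p <- c(runif(40), rbeta(10, 0.5, 20))
    q <- bh_adjust(p)
    ps <- sort(p)
    k <- max(c(0L, which(ps <= alpha * seq_along(ps) / length(ps))))
    classical <- if (k > 0) p <= ps[k] else rep(FALSE, length(p))
    expect_equal(unname(q < alpha), unname(classical), info = paste("rep", i))
  }
})

test_that("test_all_events excludes untestable tables, labels direction by
           the sign of delta PSI, and reports a gene summary", {
  tab <- data.frame(
    event_id = c("e1", "e2", "e3", "e4"),
    type = c("SE", "SE", "IR", "SE"),
    gene_id = c("g1", "g1", "g2", "g3"),
    n_inc_junctions = c(2L, 2L, 2L, 2L), n_exc_junctions = 1L,
    inc_control = c(20L, 0L, 0L, 18L), exc_control = c(0L, 0L, 10L, 2L),
    inc_treated = c(0L, 0L, 10L, 17L), exc_treated = c(20L, 5L, 10L, 3L),
    stringsAsFactors = FALSE)
  res <- test_all_events(tab, alpha = 0.05)
  expect_false(res$tested[2])            # all-zero control row
  expect_true(is.na(res$p[2]))
  expect_true(res$significant[1])
  expect_equal(res$direction[1], "activated")   # inclusion falls on knockdown
  expect_true(res$significant[3])
  expect_equal(res$direction[3], "repressed")
  expect_false(res$significant[4])
  s <- attr(res, "summary")
  expect_equal(unname(s["n_tested"]), 3L)
  expect_equal(unname(s["n_genes_significant"]), 2L)
  # q is BH over the tested events only
  expect_equal(res$q[res$tested], bh_adjust(res$p[res$tested]))
})

test_that("sample label collision is rejected when merging counts", {
  ev <- data.frame(event_id = "e1", type = "SE", gene_id = "g1",
                   n_inc_junctions = 2L, n_exc_junctions = 1L)
  qc <- data.frame(event_id = "e1", sample = "control",
                   inclusion_reads = 5L, exclusion_reads = 3L)
  qt <- qc
  expect_error(merge_event_counts(ev, qc, qt), "collision")
  qt$sample <- "treated"
  m <- merge_event_counts(ev, qc, qt)
  expect_equal(m$inc_treated, 5L)
})

test_that("planted splicing changes are detected with high power while null
           events stay controlled", {
  tab <- simulate_event_counts(
    psi_control = c(rep(0.5, 100), rep(0.3, 20)),
    psi_treated = c(rep(0.5, 100), rep(0.7, 20)),
    reads_per_event = 200, seed = 91)
  res <- test_all_events(tab)
  planted <- c(rep(FALSE, 100), rep(TRUE, 20))
  expect_gte(sum(res$significant[planted]), 18)
  expect_true(all(res$direction[res$significant & planted] == "repressed"))
  fdp <- sum(res$significant & !planted) / max(1, sum(res$significant))
  expect_lte(fdp, 0.2)   # single-replicate guard; the long-run FDR is
                         # checked over replicates in the acceptance suite
})

test_that("RPKM formula and expression filter follow the stated thresholds", {
  gc <- data.frame(gene_id = "g1", count_control = 100, count_treated = 100)
  r <- rpkm_and_expression_filter(gc, c(g1 = 1000), c(control = 1e6, treated = 1e6))
  expect_equal(r$rpkm_control, 100)
  expect_equal(r$rpkm_treated, 100)
  gc2 <- data.frame(gene_id = c("gA", "gB", "gC"),
                    count_control = c(4, 10, 10),
                    count_treated = c(3, 21, 19))
  lens <- c(gA = 10000, gB = 10000, gC = 10000)
  tot <- c(control = 1e6, treated = 1e6)
  r2 <- rpkm_and_expression_filter(gc2, lens, tot)
  expect_equal(r2$pass, c(FALSE, TRUE, FALSE))  # (0.4,0.3) fails RPKM floor;
                                                # fold 2.1 passes; 1.9 fails
  expect_error(rpkm_and_expression_filter(gc, c(g1 = 0), tot), "zero gene length")
  expect_error(rpkm_and_expression_filter(gc, c(g1 = 1000),
                                          c(control = 0, treated = 1)), "> 0")
})
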