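# Per-event differential-splicing statistics: Fisher's exact test on the
# 2x2 inclusion/exclusion x condition table, BH correction across all tested
# events, direction calls and inclusion fold changes, plus the RPKM-based
# expression filter.

#' Two-sided Fisher's exact test p-value for a 2x2 table
#'
#' Sums the hypergeometric probabilities, over all tables with the observed
#' margins, of every table whose probability does not exceed that of the
#' observed table (within relative tolerance 1e-7). A table with an all-zero
#' row or column carries no information about association and is an error.
#'
#' @param a,b,c,d inclusion/exclusion counts for control (a, b) and treated
#'   (c, d).
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("untestable table: an all-zero row or column")
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#' returned in the original order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Merge event counts from two samples into a test-ready table
#'
#' @param events data.frame with event_id, type, gene_id,
#'   n_inc_junctions, n_exc_junctions.
#' @param counts_control,counts_treated data.frames from [quantify_events()];
#'   their `sample` labels must differ.
#' @return data.frame with one row per event and count columns per condition.
#' @export
merge_event_counts <- function(events, counts_control, counts_treated) {
  sc <- unique(counts_control$sample); st <- unique(counts_treated$sample)
  if (length(intersect(sc, st)) > 0L) stop("sample name collision: ", sc[1])
  mc <- match(events$event_id, counts_control$event_id)
  mt <- match(events$event_id, counts_treated$event_id)
  if (any(is.na(mc)) || any(is.na(mt))) stop("missing counts for some events")
  data.frame(events[, c("event_id", "type", "gene_id",
                        "n_inc_junctions", "n_exc_junctions")],
             inc_control = counts_control$inclusion_reads[mc],
             exc_control = counts_control$exclusion_reads[mc],
             inc_treated = counts_treated$inclusion_reads[mt],
             exc_treated = counts_treated$exclusion_reads[mt],
             stringsAsFactors = FALSE)
}

#' Test all events for differential splicing
#'
#' For each event, a Fisher's exact test on the 2x2 table of inclusion and
#' exclusion read counts in the two conditions; BH adjustment is applied once
#' across all testable events (all-zero-row/column tables are excluded before
#' correction and get NA p/q). The treated condition is a regulator
#' knockdown, so a significant drop in inclusion (delta PSI < 0) labels the
#' event "activated" by the regulator and a rise labels it "repressed".
#'
#' @param tab data.frame as produced by [merge_event_counts()] or
#'   [simulate_event_counts()].
#' @param alpha BH significance level (default 0.05).
#' @return data.frame of per-event results with attribute `summary`
#'   (n_tested, n_significant, n_genes_significant).
#' @export
test_all_events <- function(tab, alpha = 0.05) {
  a <- tab$inc_control; b <- tab$exc_control
  cc <- tab$inc_treated; d <- tab$exc_treated
  testable <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  p <- rep(NA_real_, nrow(tab))
  for (i in which(testable)) p[i] <- fisher_exact_two_sided(a[i], b[i], cc[i], d[i])
  q <- rep(NA_real_, nrow(tab))
  if (any(testable)) q[testable] <- bh_adjust(p[testable])
  psi_c <- compute_psi(a, b, tab$n_inc_junctions, tab$n_exc_junctions)
  psi_t <- compute_psi(cc, d, tab$n_inc_junctions, tab$n_exc_junctions)
  delta <- psi_t - psi_c
  fold <- ifelse(is.na(psi_c) | is.na(psi_t), NA_real_,
                 ifelse(psi_c == 0, Inf, psi_t / psi_c))
  sig <- !is.na(q) & q < alpha
  dir <- rep(NA_character_, nrow(tab))
  dir[sig & delta < 0] <- "activated"
  dir[sig & delta > 0] <- "repressed"
  res <- data.frame(
    event_id = tab$event_id, type = tab$type, gene_id = tab$gene_id,
    inc_control = a, exc_control = b, inc_treated = cc, exc_treated = d,
    psi_control = psi_c, psi_treated = psi_t, delta_psi = delta,
    inclusion_fold_change = fold, p = p, q = q, tested = testable,
    significant = sig, direction = dir, stringsAsFactors = FALSE)
  attr(res, "summary") <- c(
    n_tested = sum(testable), n_significant = sum(sig),
    n_genes_significant = length(unique(res$gene_id[sig])))
  res
}

#' RPKM computation and expression-change filter
#'
#' RPKM = 1e9 * count / (total * length). A gene passes when the larger of
#' its two RPKM values is at least `min_rpkm` and the fold change between
#' conditions (larger over smaller) exceeds `min_fold`.
#'
#' @param gene_counts data.frame with gene_id, count_control, count_treated.
#' @param gene_lengths named numeric vector (nt per gene).
#' @param totals named numeric vector c(control=, treated=) of uniquely
#'   mapped reads per sample.
#' @param min_rpkm,min_fold filter thresholds (defaults 0.5 and 2).
#' @return data.frame with RPKM per condition, fold change, and `pass`.
#' @export
rpkm_and_expression_filter <- function(gene_counts, gene_lengths, totals,
                                       min_rpkm = 0.5, min_fold = 2) {
  if (any(totals <= 0)) stop("sample totals must be > 0")
  len <- gene_lengths[gene_counts$gene_id]
  if (any(is.na(len)) || any(len <= 0)) stop("missing or zero gene length")
  rc <- 1e9 * gene_counts$count_control / (totals[["control"]] * len)
  rt <- 1e9 * gene_counts$count_treated / (totals[["treated"]] * len)
  fold <- pmax(rc, rt) / pmin(rc, rt)
  pass <- pmax(rc, rt) >= min_rpkm & fold > min_fold
  data.frame(gene_id = gene_counts$gene_id, rpkm_control = rc,
             rpkm_treated = rt, fold_change = fold, pass = pass,
             row.names = NULL, stringsAsFactors = FALSE)
}
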