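# Independent oracles and tiny fixture builders used across the suite.

# mismatch counts of `read` against every start position of `target`
# (plain sliding Hamming scan; independent of the package's seeded index)
hamming_scan <- function(read, target) {
  L <- nchar(read); N <- nchar(target)
  if (N < L) return(integer(0))
  r <- utf8ToInt(read); t <- utf8ToInt(target)
  n_pos <- N - L + 1L
  mism <- integer(n_pos)
  for (k in seq_len(L)) mism <- mism + (t[k:(k + n_pos - 1L)] != r[k])
  mism
}

# every placement of one read with <= max_mm mismatches over both genome
# strands and the sense junction library, with the spanning rule applied;
# mirrors the alignment contract by exhaustive search
brute_force_placements <- function(rseq, genome, lib, max_mm = 3L) {
  L <- nchar(rseq)
  out <- list()
  for (ctg in names(genome)) {
    fwd <- hamming_scan(rseq, genome[[ctg]])
    for (i in which(fwd <= max_mm)) {
      out[[length(out) + 1L]] <- data.frame(
        target_type = "genome", target = ctg, start = i - 1L, strand = "+",
        mismatches = fwd[i], overhang = NA_integer_)
    }
    rev <- hamming_scan(rseq, dasmap::revcomp(genome[[ctg]]))
    N <- nchar(genome[[ctg]])
    for (i in which(rev <= max_mm)) {
      out[[length(out) + 1L]] <- data.frame(
        target_type = "genome", target = ctg, start = N - (i - 1L) - L,
        strand = "-", mismatches = rev[i], overhang = NA_integer_)
    }
  }
  if (nrow(lib) > 0L) for (j in seq_len(nrow(lib))) {
    if (nchar(lib$seq[j]) < L) next
    mm <- hamming_scan(rseq, lib$seq[j])
    for (i in which(mm <= max_mm)) {
      lstart <- i - 1L
      left <- lib$left_len[j] - lstart
      right <- lstart + L - lib$left_len[j]
      if (left < 1L || right < 1L) next
      out[[length(out) + 1L]] <- data.frame(
        target_type = "junction", target = lib$junction_id[j], start = lstart,
        strand = "+", mismatches = mm[i], overhang = min(left, right))
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# unique-best resolution of brute-force placements (the aligner's contract)
brute_force_unique <- function(rseq, genome, lib, max_mm = 3L) {
  pl <- brute_force_placements(rseq, genome, lib, max_mm)
  if (is.null(pl)) return(NULL)
  best <- min(pl$mismatches)
  at <- which(pl$mismatches == best)
  if (length(at) != 1L) return("ambiguous")
  pl[at, , drop = FALSE]
}

# two-sided Fisher p by literal enumeration with log-binomials (no dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(x)
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1), numeric(1))
  probs <- exp(lp)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# textbook BH step-up, computed from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# a hand-built two-exon gene on a tiny explicit genome
toy_two_exon <- function(strand = "+") {
  seqs <- paste(rep(c("ACGTACGTAC", "GGTTCCAAGG", "TTGACCTGAA",
                      "CATGCATGCA", "GCGCATATGC"), 4), collapse = "")
  genome <- dasmap:::validate_genome(c(c1 = seqs))
  gm <- gene_model("gX", "c1", strand,
                   list(tA = data.frame(start = c(10L, 60L), end = c(30L, 85L))))
  list(genome = genome, gene = gm)
}
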