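# End-to-end orchestration: simulate -> junction library -> align -> count ->
# events -> differential test -> RNA map, with a manifest recording inputs,
# parameters and seeds so reruns are reproducible.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# union-of-exons length per gene
gene_union_lengths <- function(genes) {
  vapply(genes, function(gm) {
    ex <- unique(do.call(rbind, unname(gm$transcripts)))
    ex <- ex[order(ex$start), , drop = FALSE]
    tot <- 0L; cur_s <- ex$start[1L]; cur_e <- ex$end[1L]
    if (nrow(ex) > 1L) for (k in 2L:nrow(ex)) {
      if (ex$start[k] <= cur_e) cur_e <- max(cur_e, ex$end[k])
      else { tot <- tot + (cur_e - cur_s); cur_s <- ex$start[k]; cur_e <- ex$end[k] }
    }
    as.numeric(tot + (cur_e - cur_s))
  }, numeric(1))
}

# uniquely-mapped read count per gene (genome alignments by position,
# junction alignments by the junction's gene)
gene_read_counts <- function(alignments, genes) {
  spans <- t(vapply(genes, function(gm) {
    ex <- do.call(rbind, unname(gm$transcripts))
    c(min(ex$start), max(ex$end))
  }, numeric(2)))
  counts <- setNames(numeric(length(genes)), names(genes))
  g <- alignments[alignments$target_type == "genome", , drop = FALSE]
  for (gid in names(genes)) {
    counts[gid] <- sum(g$start >= spans[gid, 1] & g$start < spans[gid, 2])
  }
  j <- alignments[alignments$target_type == "junction", , drop = FALSE]
  if (nrow(j) > 0L) {
    jg <- vapply(strsplit(j$target, "|", fixed = TRUE), `[`, character(1), 1L)
    tj <- table(jg)
    counts[names(tj)] <- counts[names(tj)] + as.numeric(tj)
  }
  counts
}

#' Run the full differential-splicing pipeline on a simulation
#'
#' Executes every stage in order, writing each stage's tables under `dir`
#' and a `manifest.json` with parameters, the seed, file checksums and the
#' package version. Reruns with the same configuration and seed are
#' bitwise-identical.
#'
#' @param config a [sim_config()].
#' @param dir run directory (created).
#' @param alpha BH significance level (default 0.05).
#' @param max_mismatches,min_overhang,min_independent alignment/counting
#'   parameters (defaults 3, 6, 2).
#' @param run_rna_map build motif maps over significant cassette exons
#'   (default TRUE; skipped with a note when the regulated sets are empty).
#' @param control_q_min minimum q-value for an event to enter the RNA-map
#'   control pool (default 0.5).
#' @return the run directory, invisibly; stage outputs live in `dir`.
#' @export
run_pipeline <- function(config, dir, alpha = 0.05, max_mismatches = 3L,
                         min_overhang = 6L, min_independent = 2L,
                         run_rna_map = TRUE, control_q_min = 0.5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  sim <- stage("simulate", {
    s <- simulate_annotation(config)
    write_fasta(s$genome, file.path(dir, "genome.fa"))
    write_gtf(s$genes, file.path(dir, "annotation.gtf"))
    write_tsv(s$truth$events, file.path(dir, "truth_events.tsv"))
    write_tsv(s$truth$motifs, file.path(dir, "truth_motifs.tsv"))
    s
  })
  reads <- stage("simulate", simulate_reads(sim, dir))

  lib <- stage("junctions", {
    l <- build_junction_library(sim$genes, sim$genome, config$read_len,
                                min_overhang)
    write_junction_library(l, file.path(dir, "junctions.fa"),
                           file.path(dir, "junctions.tsv"))
    l
  })

  aln <- list(); counts <- list()
  stage("align", {
    index <- build_align_index(sim$genome, lib, config$read_len, max_mismatches)
    for (cond in c("control", "treated")) {
      rd <- read_fastq(reads$fastq[[cond]])
      a <- align_reads(rd, index = index, max_mismatches = max_mismatches)
      aln[[cond]] <- a
      counts[[cond]] <- count_junctions(a, min_overhang, min_independent)
      write_tsv(a, file.path(dir, paste0("alignments_", cond, ".tsv")))
      write_tsv(counts[[cond]], file.path(dir, paste0("junction_counts_", cond, ".tsv")))
      s <- attr(a, "summary")
      message(sprintf("[align] %s: %d unique, %d ambiguous, %d unaligned of %d",
                      cond, s["unique"], s["ambiguous"], s["unaligned"], s["total"]))
    }
  })

  events <- stage("events", {
    ev <- enumerate_events(sim$genes)
    write_tsv(ev, file.path(dir, "events.tsv"))
    ev
  })

  res <- stage("test", {
    qc <- quantify_events(events, counts$control, aln$control, "control",
                          config$read_len, min_overhang, min_independent)
    qt <- quantify_events(events, counts$treated, aln$treated, "treated",
                          config$read_len, min_overhang, min_independent)
    write_tsv(rbind(qc, qt), file.path(dir, "event_counts.tsv"))
    tab <- merge_event_counts(events, qc, qt)
    r <- test_all_events(tab, alpha)
    write_tsv(r, file.path(dir, "splicing_results.tsv"))
    s <- attr(r, "summary")
    message(sprintf("[test] %d events in %d genes significant (of %d tested)",
                    s["n_significant"], s["n_genes_significant"], s["n_tested"]))
    r
  })

  stage("expression", {
    lens <- gene_union_lengths(sim$genes)
    gc <- data.frame(gene_id = names(sim$genes),
                     count_control = gene_read_counts(aln$control, sim$genes),
                     count_treated = gene_read_counts(aln$treated, sim$genes))
    totals <- c(control = unname(attr(aln$control, "summary")["unique"]),
                treated = unname(attr(aln$treated, "summary")["unique"]))
    write_tsv(rpkm_and_expression_filter(gc, lens, totals),
              file.path(dir, "expression.tsv"))
  })

  rna_map_run <- FALSE
  if (run_rna_map) stage("rna_map", {
    se <- merge(res[res$type == "SE", c("event_id", "significant", "direction", "q")],
                as.data.frame(events)[, c("event_id", "gene_id", "alt_start", "alt_end")],
                by = "event_id")
    act <- se[se$significant & se$direction == "activated", , drop = FALSE]
    rep_ <- se[se$significant & se$direction == "repressed", , drop = FALSE]
    ctl <- se[!se$significant & !is.na(se$q) & se$q >= control_q_min, , drop = FALSE]
    if (nrow(act) > 0L && nrow(rep_) > 0L && nrow(ctl) > 0L) {
      prof <- build_motif_map(list(activated = act, repressed = rep_,
                                   control = ctl), sim$genes, sim$genome)
      write_tsv(prof, file.path(dir, "rna_map_profiles.tsv"))
      enr <- upstream_window_enrichment(rep_, ctl, sim$genes, sim$genome,
                                        n_perm = 1000L, seed = config$seed)
      write_tsv(data.frame(density_ratio = enr$density_ratio, p = enr$p,
                           mean_repressed = enr$mean_repressed,
                           mean_control = enr$mean_control,
                           window_lo = enr$window[1], window_hi = enr$window[2],
                           n_truncated = enr$n_truncated),
                file.path(dir, "rna_map_enrichment.tsv"))
      rna_map_run <- TRUE
    } else {
      message("[rna_map] skipped: need non-empty activated, repressed and control sets")
    }
  })

  files <- list.files(dir, pattern = "\\.(tsv|fa|gtf|fastq)$", full.names = TRUE)
  manifest <- list(
    package = "dasmap",
    version = as.character(utils::packageVersion("dasmap")),
    seed = config$seed,
    parameters = list(read_len = config$read_len, depth = config$depth,
                      error_rate = config$error_rate, alpha = alpha,
                      max_mismatches = max_mismatches,
                      min_overhang = min_overhang,
                      min_independent = min_independent),
    rna_map_run = rna_map_run,
    checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Summarize a completed pipeline run
#'
#' A pure function of the run directory: tallies significant events per type
#' and direction, genes affected, and — when ground truth is present —
#' sensitivity and false-discovery proportion against the planted events.
#'
#' @param dir run directory from [run_pipeline()].
#' @return list with `events_by_type`, `direction`, `n_genes`, and
#'   optionally `recovery`; also written to `summary.txt` in `dir`.
#' @export
summarize_run <- function(dir) {
  resp <- file.path(dir, "splicing_results.tsv")
  if (!file.exists(resp)) stop("no splicing_results.tsv in ", dir)
  res <- read_tsv(resp)
  sig <- res[res$significant %in% TRUE, , drop = FALSE]
  out <- list(
    n_tested = sum(res$tested %in% TRUE),
    n_significant = nrow(sig),
    n_genes = length(unique(sig$gene_id)),
    events_by_type = table(factor(sig$type, levels = AS_TYPES)),
    direction = table(factor(sig$direction, levels = c("activated", "repressed"))))
  tp <- file.path(dir, "truth_events.tsv")
  if (file.exists(tp)) {
    truth <- read_tsv(tp)
    truth$planted <- truth$psi_control != truth$psi_treated
    m <- merge(res, truth[, c("gene_id", "type", "planted")],
               by = c("gene_id", "type"), all.x = TRUE)
    tp_n <- sum(m$significant %in% TRUE & m$planted %in% TRUE)
    fp_n <- sum(m$significant %in% TRUE & m$planted %in% FALSE)
    out$recovery <- list(
      n_planted = sum(truth$planted),
      sensitivity = if (sum(truth$planted) > 0) tp_n / sum(truth$planted) else NA,
      false_discoveries = fp_n,
      fdp = if (nrow(sig) > 0) fp_n / nrow(sig) else 0)
  }
  lines <- c(
    sprintf("%d events in %d genes significant (of %d tested)",
            out$n_significant, out$n_genes, out$n_tested),
    paste("by type:", paste(sprintf("%s=%d", names(out$events_by_type),
                                    out$events_by_type), collapse = " ")),
    paste("direction:", paste(sprintf("%s=%d", names(out$direction),
                                      out$direction), collapse = " ")))
  if (!is.null(out$recovery)) {
    lines <- c(lines, sprintf(
      "ground truth: %d planted, sensitivity %.3f, %d false discoveries (FDP %.3f)",
      out$recovery$n_planted, out$recovery$sensitivity,
      out$recovery$false_discoveries, out$recovery$fdp))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  out
}
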