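# Synthetic two-condition RNA-seq with known splicing ground truth.
#
# Each requested AS event is realized as one gene with exactly two isoforms
# that differ only by that event. Genes are laid out on a single contig,
# alternating strand, separated by neutral spacer sequence. Reads are
# single-end, sense-agnostic downstream (the aligner searches both strands).

AS_TYPES <- c("SE", "IR", "A5SS", "A3SS", "MXE", "AFE", "ALE")

#' Simulation configuration
#'
#' @param seed integer seed driving every random choice (mandatory).
#' @param read_len read length, 50 or 75 nt.
#' @param events_per_type named integer vector over a subset of
#'   SE, IR, A5SS, A3SS, MXE, AFE, ALE.
#' @param psi data.frame with columns `event_id`, `psi_control`,
#'   `psi_treated`, or NULL for 0.5/0.5 everywhere. Event ids are
#'   `<TYPE>_<k>` with k counting within type.
#' @param depth reads per transcript-kilobase per condition.
#' @param error_rate per-base substitution probability (< 0.05).
#' @param motif_plan data.frame with columns `label` (activated / repressed /
#'   control, matched against the sign of the true delta-PSI of SE events),
#'   `anchor` ("3ss": offset 0 is the first exon base, negative offsets run
#'   into the upstream intron; "5ss": offset 0 is the first base of the
#'   downstream intron; "exon": offset from exon start), `offset` (nt) and
#'   `motif` (RNA space, e.g. "ACUAAU"). NULL for no planting.
#' @param exon_len,intron_len,spacer layout dimensions in nt; exons must be
#'   at least `2 * (read_len - 6)` and introns at least 80 nt.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, read_len = 50L,
                       events_per_type = c(SE = 1L),
                       psi = NULL, depth = 50, error_rate = 0.002,
                       motif_plan = NULL,
                       exon_len = 150L, intron_len = 250L, spacer = 300L) {
  if (missing(seed)) stop("seed is mandatory")
  if (!read_len %in% c(50L, 75L)) stop("read_len must be 50 or 75")
  if (!all(names(events_per_type) %in% AS_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(names(events_per_type), AS_TYPES), collapse = ", "))
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.05) stop("error_rate must be in [0, 0.05)")
  if (exon_len < 2L * (read_len - 6L)) stop("exon_len too short for read_len")
  if (intron_len < 80L) stop("intron_len must be >= 80")
  structure(list(seed = as.integer(seed), read_len = as.integer(read_len),
                 events_per_type = events_per_type, psi = psi, depth = depth,
                 error_rate = error_rate, motif_plan = motif_plan,
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 spacer = as.integer(spacer)),
            class = "sim_config")
}

# exon layouts in transcription-space coordinates; returns list(inc=, exc=,
# alt_start, alt_end, boundaries) where alt_* frame the defining region
event_layout <- function(type, E, I, delta = 33L) {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  switch(type,
    SE = list(inc = ex(0, E,  E + I, E + I + E,  E + 2L*I + E, E + 2L*I + 2L*E),
              exc = ex(0, E,  E + 2L*I + E, E + 2L*I + 2L*E),
              alt = c(E + I, E + I + E)),
    IR = list(inc = ex(0, 2L*E + I),                    # intron retained
              exc = ex(0, E,  E + I, 2L*E + I),
              alt = c(E, E + I)),                       # the intron
    A5SS = list(inc = ex(0, E + delta,  E + delta + I, E + delta + I + E),
                exc = ex(0, E,          E + delta + I, E + delta + I + E),
                alt = c(E, E + delta)),
    A3SS = list(inc = ex(0, E,  E + I, E + I + delta + E),
                exc = ex(0, E,  E + I + delta, E + I + delta + E),
                alt = c(E + I, E + I + delta)),
    MXE = list(inc = ex(0, E,  E + I, E + I + E,  E + 3L*I + 2L*E, E + 3L*I + 3L*E),
               exc = ex(0, E,  E + 2L*I + E, E + 2L*I + 2L*E,
                        E + 3L*I + 2L*E, E + 3L*I + 3L*E),
               alt = c(E + I, E + I + E)),
    AFE = list(inc = ex(0, E,  E + 2L*I + E, E + 2L*I + 2L*E),
               exc = ex(E + I, E + I + E,  E + 2L*I + E, E + 2L*I + 2L*E),
               alt = c(0, E)),
    ALE = list(inc = ex(0, E,  E + I, E + I + E),
               exc = ex(0, E,  E + 2L*I + E, E + 2L*I + 2L*E),
               alt = c(E + I, E + I + E)),
    stop("unknown event type: ", type))
}

# map transcription-space exon table to genomic coordinates
tx_to_genomic <- function(ex, offset, span, strand) {
  if (strand == "+") {
    data.frame(start = offset + ex$start, end = offset + ex$end)
  } else {
    g <- data.frame(start = offset + span - ex$end, end = offset + span - ex$start)
    g <- g[order(g$start), , drop = FALSE]
    rownames(g) <- NULL
    g
  }
}

# junction ids along one isoform (consecutive exon pairs, genomic coords)
isoform_junction_ids <- function(gene_id, contig, strand, ex) {
  n <- nrow(ex)
  if (n < 2L) return(character(0))
  ids <- character(n - 1L)
  for (k in seq_len(n - 1L)) {
    if (strand == "+") { donor <- ex$end[k]; acceptor <- ex$start[k + 1L] }
    else { donor <- ex$start[n - k + 1L]; acceptor <- ex$end[n - k] }
    ids[k] <- junction_id(gene_id, contig, donor, acceptor, strand)
  }
  ids
}

#' Simulate a genome and gene models carrying known AS events
#'
#' Builds a uniform-random background genome, one two-isoform gene per
#' requested event, and plants RNA-binding motifs (in DNA space, on the sense
#' strand) at fixed offsets around cassette exons according to the motif
#' plan. The returned ground truth records, per event, the true type,
#' condition-wise PSI, the defining genomic interval, the evidence junction
#' ids, and every planted motif position.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (`genome_seq`), `genes` (named list of
#'   `gene_model`) and `truth` (list with `events` and `motifs` data.frames).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  E <- config$exon_len; I <- config$intron_len; SP <- config$spacer
  contig <- "chrS"

  specs <- list()
  for (type in names(config$events_per_type)) {
    n <- config$events_per_type[[type]]
    if (n > 0L) for (k in seq_len(n))
      specs[[length(specs) + 1L]] <- list(type = type, idx = k)
  }
  if (length(specs) == 0L) stop("no events requested")

  # layouts and genomic offsets
  layouts <- lapply(specs, function(s) event_layout(s$type, E, I))
  spans <- vapply(layouts, function(l) max(l$inc$end, l$exc$end), numeric(1))
  offsets <- SP + cumsum(c(0, head(spans + SP, -1)))
  total_len <- offsets[length(offsets)] + spans[length(spans)] + SP

  seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  genome_str <- paste(seq_chars, collapse = "")

  genes <- list()
  ev_rows <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]; lay <- layouts[[i]]
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%03d", i)
    eid <- sprintf("%s_%d", s$type, s$idx)
    span <- spans[i]; off <- offsets[i]
    inc_g <- tx_to_genomic(lay$inc, off, span, strand)
    exc_g <- tx_to_genomic(lay$exc, off, span, strand)
    # MXE inclusion is defined as the genomically upstream alternative exon:
    # on the - strand the mirrored layout makes the "exc" isoform carry it
    if (s$type == "MXE" && strand == "-") { tmp <- inc_g; inc_g <- exc_g; exc_g <- tmp }
    txs <- setNames(list(inc_g, exc_g), paste0(gid, c(".t1", ".t2")))
    genes[[gid]] <- gene_model(gid, contig, strand, txs)

    alt <- lay$alt
    if (strand == "+") alt_g <- off + alt else alt_g <- off + span - rev(alt)
    jinc <- isoform_junction_ids(gid, contig, strand, inc_g)
    jexc <- isoform_junction_ids(gid, contig, strand, exc_g)
    inc_only <- setdiff(jinc, jexc); exc_only <- setdiff(jexc, jinc)
    if (s$type == "IR") {
      n_inc <- 2L   # the two exon-intron boundaries
    } else {
      n_inc <- length(inc_only)
    }
    ev_rows[[i]] <- data.frame(
      event_id = eid, type = s$type, gene_id = gid, contig = contig,
      strand = strand, alt_start = alt_g[1], alt_end = alt_g[2],
      inc_junctions = paste(inc_only, collapse = ","),
      exc_junctions = paste(exc_only, collapse = ","),
      n_inc_junctions = n_inc, n_exc_junctions = length(exc_only),
      psi_control = 0.5, psi_treated = 0.5, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_rows)
  rownames(events) <- NULL

  if (!is.null(config$psi)) {
    m <- match(events$event_id, config$psi$event_id)
    hit <- !is.na(m)
    events$psi_control[hit] <- config$psi$psi_control[m[hit]]
    events$psi_treated[hit] <- config$psi$psi_treated[m[hit]]
  }
  d <- events$psi_treated - events$psi_control
  # treated = regulator knockdown: inclusion falling means the regulator
  # activated inclusion
  events$label <- ifelse(d < 0, "activated", ifelse(d > 0, "repressed", "control"))

  # ---- motif planting (SE events only; the RNA map is about cassette exons)
  motifs <- data.frame(event_id = character(0), label = character(0),
                       anchor = character(0), offset = integer(0),
                       motif = character(0), contig = character(0),
                       gstart = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(config$motif_plan) && nrow(config$motif_plan) > 0L) {
    se <- events[events$type == "SE", , drop = FALSE]
    for (r in seq_len(nrow(config$motif_plan))) {
      mp <- config$motif_plan[r, ]
      motif_dna <- chartr("U", "T", toupper(mp$motif))
      L <- nchar(motif_dna)
      targets <- se[se$label == mp$label, , drop = FALSE]
      for (t in seq_len(nrow(targets))) {
        tv <- targets[t, ]
        ok <- switch(mp$anchor,
          "3ss"  = (mp$offset >= -I && mp$offset + L <= E),
          "5ss"  = (mp$offset >= 0 && mp$offset + L <= I),
          "exon" = (mp$offset >= 0 && mp$offset + L <= E),
          stop("unknown motif anchor: ", mp$anchor))
        if (!ok) stop("motif does not fit inside its region (anchor ",
                      mp$anchor, ", offset ", mp$offset, ")")
        if (tv$strand == "+") {
          anchor_pos <- switch(mp$anchor, "3ss" = tv$alt_start,
                               "exon" = tv$alt_start, "5ss" = tv$alt_end)
          gstart <- anchor_pos + mp$offset
          substr(genome_str, gstart + 1L, gstart + L) <- motif_dna
        } else {
          # sense offset o from the anchor maps to genomic [anchor - o - L, anchor - o)
          anchor_pos <- switch(mp$anchor, "3ss" = tv$alt_end,
                               "exon" = tv$alt_end, "5ss" = tv$alt_start)
          gstart <- anchor_pos - mp$offset - L
          substr(genome_str, gstart + 1L, gstart + L) <- revcomp(motif_dna)
        }
        motifs <- rbind(motifs, data.frame(
          event_id = tv$event_id, label = mp$label, anchor = mp$anchor,
          offset = mp$offset, motif = toupper(mp$motif), contig = contig,
          gstart = gstart, strand = tv$strand, stringsAsFactors = FALSE))
      }
    }
  }

  genome <- validate_genome(setNames(genome_str, contig))
  validate_models(genes, genome)
  list(genome = genome, genes = genes,
       truth = list(events = events, motifs = motifs, config = config))
}

# mRNA sequence of a transcript (sense strand)
transcript_mrna <- function(genome, gm, tid) {
  ex <- gm$transcripts[[tid]]
  parts <- vapply(seq_len(nrow(ex)), function(k)
    genome_subseq(genome, gm$contig, ex$start[k], ex$end[k]), character(1))
  s <- paste(parts, collapse = "")
  if (gm$strand == "-") revcomp(s) else s
}

# mRNA positions (in sense coordinates) of the junctions of a transcript,
# paired with their junction ids
transcript_junction_positions <- function(gm, tid) {
  ex <- gm$transcripts[[tid]]
  n <- nrow(ex)
  if (n < 2L) return(data.frame(pos = integer(0), junction_id = character(0)))
  lens <- ex$end - ex$start
  if (gm$strand == "-") lens <- rev(lens)
  data.frame(pos = cumsum(lens)[-n],
             junction_id = isoform_junction_ids(gm$gene_id, gm$contig, gm$strand, ex),
             stringsAsFactors = FALSE)
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  L <- nchar(reads[1])
  n <- length(reads)
  hit <- which(runif(n * L) < error_rate)
  if (length(hit) == 0L) return(reads)
  ri <- ((hit - 1L) %/% L) + 1L
  pos <- ((hit - 1L) %% L) + 1L
  for (k in seq_along(hit)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(reads[ri[k]], pos[k], pos[k]) <- new
  }
  reads
}

#' Simulate single-end reads for both conditions
#'
#' PSI is the molar fraction of a gene's transcripts carrying the inclusion
#' isoform, so under uniform sequencing each read originates from the
#' inclusion isoform with probability `psi * L_inc / (psi * L_inc +
#' (1 - psi) * L_exc)` (molecule pick weighted by mRNA length), its start is
#' uniform over mRNA positions admitting a full-length read, and bases are
#' substituted i.i.d. at the configured error rate. Reads are written as
#' Phred33 FASTQ (constant quality "I") together with a read-origin table
#' recording isoform of origin and, for junction-spanning reads, the true
#' junction and its two-sided overhang.
#'
#' @param sim result of [simulate_annotation()].
#' @param dir output directory (created if needed).
#' @return list with `fastq` (named paths), `origins` (data.frame), and
#'   `origins_path`.
#' @export
simulate_reads <- function(sim, dir) {
  config <- sim$truth$config
  genome <- sim$genome; genes <- sim$genes; events <- sim$truth$events
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- config$read_len
  paths <- c(control = file.path(dir, "control.fastq"),
             treated = file.path(dir, "treated.fastq"))
  all_origins <- list()
  for (ci in 1:2) {
    cond <- names(paths)[ci]
    set.seed((config$seed + ci * 7919L) %% .Machine$integer.max)
    fq <- character(0)
    for (gi in seq_len(nrow(events))) {
      ev <- events[gi, ]
      gm <- genes[[ev$gene_id]]
      tids <- names(gm$transcripts)
      mrnas <- setNames(vapply(tids, function(t) transcript_mrna(genome, gm, t),
                               character(1)), tids)
      if (any(nchar(mrnas) < L)) stop("transcript shorter than read length")
      psi <- if (cond == "control") ev$psi_control else ev$psi_treated
      n <- max(1L, as.integer(round(config$depth * mean(nchar(mrnas)) / 1000)))
      w <- psi * nchar(mrnas[[1L]]) /
        (psi * nchar(mrnas[[1L]]) + (1 - psi) * nchar(mrnas[[2L]]))
      iso <- ifelse(stats::rbinom(n, 1L, w) == 1L, tids[1L], tids[2L])
      starts <- integer(n)
      seqs <- character(n)
      jxn <- rep(NA_character_, n)
      ohl <- rep(NA_integer_, n); ohr <- rep(NA_integer_, n)
      jpos <- lapply(setNames(tids, tids), function(t)
        transcript_junction_positions(gm, t))
      for (t in tids) {
        idx <- which(iso == t)
        if (length(idx) == 0L) next
        len <- nchar(mrnas[[t]])
        st <- sample.int(len - L + 1L, length(idx), replace = TRUE) - 1L
        starts[idx] <- st
        seqs[idx] <- substring(mrnas[[t]], st + 1L, st + L)
        jp <- jpos[[t]]
        if (nrow(jp) > 0L) for (k in seq_len(nrow(jp))) {
          sp <- which(st < jp$pos[k] & st + L > jp$pos[k])
          if (length(sp) > 0L) {
            jxn[idx[sp]] <- jp$junction_id[k]
            ohl[idx[sp]] <- jp$pos[k] - st[sp]
            ohr[idx[sp]] <- st[sp] + L - jp$pos[k]
          }
        }
      }
      seqs <- inject_errors(seqs, config$error_rate)
      ids <- sprintf("%s:%s:%06d", cond, ev$gene_id, seq_len(n))
      fq <- c(fq, as.vector(rbind(paste0("@", ids), seqs, "+",
                                  strrep("I", L))))
      all_origins[[paste(cond, ev$gene_id)]] <- data.frame(
        read_id = ids, condition = cond, gene_id = ev$gene_id,
        event_id = ev$event_id, transcript_id = iso,
        isoform = ifelse(iso == tids[1L], "inc", "exc"),
        mrna_start = starts, junction_id = jxn,
        overhang_left = ohl, overhang_right = ohr,
        stringsAsFactors = FALSE)
    }
    writeLines(fq, paths[[cond]])
  }
  origins <- do.call(rbind, all_origins)
  rownames(origins) <- NULL
  op <- file.path(dir, "read_origins.tsv")
  write.table(origins, op, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fastq = paths, origins = origins, origins_path = op)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Simulate inclusion/exclusion junction counts directly
#'
#' Generates per-event read counts at the quantification level (one inclusion
#' and one exclusion junction per event, reads split binomially by the true
#' PSI of each condition), bypassing read-level simulation. Used for
#' statistical power and FDR studies of the event test.
#'
#' @param psi_control,psi_treated numeric vectors (one entry per event).
#' @param reads_per_event reads per event per condition (scalar or vector).
#' @param seed integer seed.
#' @return data.frame with per-event counts for both conditions.
#' @export
simulate_event_counts <- function(psi_control, psi_treated, reads_per_event,
                                  seed) {
  stopifnot(length(psi_control) == length(psi_treated))
  set.seed(seed)
  n_ev <- length(psi_control)
  n <- rep_len(reads_per_event, n_ev)
  a <- stats::rbinom(n_ev, n, psi_control)
  c_ <- stats::rbinom(n_ev, n, psi_treated)
  data.frame(event_id = sprintf("ev%04d", seq_len(n_ev)),
             type = "SE", gene_id = sprintf("g%04d", seq_len(n_ev)),
             n_inc_junctions = 1L, n_exc_junctions = 1L,
             inc_control = a, exc_control = n - a,
             inc_treated = c_, exc_treated = n - c_,
             psi_true_control = psi_control, psi_true_treated = psi_treated,
             stringsAsFactors = FALSE)
}
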