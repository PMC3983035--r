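# Seven-type alternative-splicing event calling from transcript models and
# junction-level quantification of inclusion/exclusion evidence.

# junction id between two genomically adjacent exons (left = smaller coords)
junction_between <- function(gene_id, contig, strand, left, right) {
  if (strand == "+") junction_id(gene_id, contig, left["end"], right["start"], strand)
  else junction_id(gene_id, contig, right["start"], left["end"], strand)
}

exon_key <- function(ex) paste(ex$start, ex$end, sep = "-")

# classify the differences between one ordered transcript pair; returns a
# list of event rows (t1 is the first-listed transcript)
classify_pair <- function(gm, ex1, ex2) {
  g <- gm$gene_id; ctg <- gm$contig; strand <- gm$strand
  k1 <- exon_key(ex1); k2 <- exon_key(ex2)
  anchors <- intersect(k1, k2)
  a1 <- match(anchors, k1); a2 <- match(anchors, k2)
  # blocks of non-shared exons between consecutive anchors (and at termini)
  bounds1 <- c(0L, a1, nrow(ex1) + 1L)
  bounds2 <- c(0L, a2, nrow(ex2) + 1L)
  events <- list()
  emit <- function(type, alt, alt2, inc, exc, n_inc, n_exc, b1 = NA, b2 = NA,
                   idc = alt) {
    events[[length(events) + 1L]] <<- data.frame(
      event_id = sprintf("%s:%s:%d-%d", g, type, idc[1], idc[2]),
      type = type, gene_id = g, contig = ctg, strand = strand,
      alt_start = alt[1], alt_end = alt[2],
      alt2_start = alt2[1], alt2_end = alt2[2],
      inc_junctions = paste(inc, collapse = ","),
      exc_junctions = paste(exc, collapse = ","),
      n_inc_junctions = n_inc, n_exc_junctions = n_exc,
      b1 = b1, b2 = b2, stringsAsFactors = FALSE)
  }
  jb <- function(left, right) junction_between(g, ctg, strand,
                                               c(start = left$start, end = left$end),
                                               c(start = right$start, end = right$end))
  for (bi in seq_len(length(bounds1) - 1L)) {
    i1 <- bounds1[bi]; j1 <- bounds1[bi + 1L]
    i2 <- bounds2[bi]; j2 <- bounds2[bi + 1L]
    A <- if (j1 - i1 > 1L) ex1[(i1 + 1L):(j1 - 1L), , drop = FALSE] else ex1[0L, ]
    B <- if (j2 - i2 > 1L) ex2[(i2 + 1L):(j2 - 1L), , drop = FALSE] else ex2[0L, ]
    nA <- nrow(A); nB <- nrow(B)
    if (nA == 0L && nB == 0L) next
    prevA <- if (i1 >= 1L) ex1[i1, , drop = FALSE] else NULL
    nextA <- if (j1 <= nrow(ex1)) ex1[j1, , drop = FALSE] else NULL

    if ((nA == 1L && nB == 0L) || (nA == 0L && nB == 1L)) {
      # cassette exon; needs flanking anchors on both sides
      if (is.null(prevA) || is.null(nextA)) next
      cass <- if (nA == 1L) A[1L, ] else B[1L, ]
      emit("SE", c(cass$start, cass$end), c(NA, NA),
           inc = c(jb(prevA, cass), jb(cass, nextA)),
           exc = jb(prevA, nextA), n_inc = 2L, n_exc = 1L)
    } else if (nA == 1L && nB == 1L) {
      a <- A[1L, ]; b <- B[1L, ]
      if (a$start == b$start && a$end != b$end && !is.null(nextA)) {
        # differing right (genomic) edge joined to the right anchor:
        # donor side on +, acceptor side on -
        type <- if (strand == "+") "A5SS" else "A3SS"
        long <- if (a$end > b$end) a else b
        short <- if (a$end > b$end) b else a
        emit(type, c(short$end, long$end), c(NA, NA),
             inc = jb(long, nextA), exc = jb(short, nextA),
             n_inc = 1L, n_exc = 1L)
      } else if (a$end == b$end && a$start != b$start && !is.null(prevA)) {
        type <- if (strand == "+") "A3SS" else "A5SS"
        long <- if (a$start < b$start) a else b
        short <- if (a$start < b$start) b else a
        emit(type, c(long$start, short$start), c(NA, NA),
             inc = jb(prevA, long), exc = jb(prevA, short),
             n_inc = 1L, n_exc = 1L)
      } else if (a$end <= b$start || b$end <= a$start) {
        up <- if (a$start < b$start) a else b
        dn <- if (a$start < b$start) b else a
        if (!is.null(prevA) && !is.null(nextA)) {
          # mutually exclusive exons; inclusion = genomically upstream exon
          emit("MXE", c(up$start, up$end), c(dn$start, dn$end),
               inc = c(jb(prevA, up), jb(up, nextA)),
               exc = c(jb(prevA, dn), jb(dn, nextA)),
               n_inc = 2L, n_exc = 2L)
        } else if (is.null(prevA) && !is.null(nextA)) {
          # alternative terminal exons at the genomic left end; the event id
          # is canonical (upstream exon) so listing order only decides which
          # variant is labelled "inclusion"
          type <- if (strand == "+") "AFE" else "ALE"
          emit(type, c(a$start, a$end), c(b$start, b$end),
               inc = jb(a, nextA), exc = jb(b, nextA),
               n_inc = 1L, n_exc = 1L, idc = c(up$start, up$end))
        } else if (!is.null(prevA) && is.null(nextA)) {
          type <- if (strand == "+") "ALE" else "AFE"
          emit(type, c(a$start, a$end), c(b$start, b$end),
               inc = jb(prevA, a), exc = jb(prevA, b),
               n_inc = 1L, n_exc = 1L, idc = c(up$start, up$end))
        }
      }
      # overlapping exons differing at both edges: left unclassified
    } else if ((nA == 2L && nB == 1L) || (nA == 1L && nB == 2L)) {
      two <- if (nA == 2L) A else B
      one <- if (nA == 2L) B else A
      if (one$start[1L] == two$start[1L] && one$end[1L] == two$end[2L] &&
          two$end[1L] < two$start[2L]) {
        # retained intron; inclusion = retention (the unspliced isoform)
        emit("IR", c(two$end[1L], two$start[2L]), c(NA, NA),
             inc = character(0),
             exc = jb(two[1L, ], two[2L, ]),
             n_inc = 2L, n_exc = 1L,
             b1 = two$end[1L], b2 = two$start[2L])
      }
    }
    # larger blocks: complex/nested events, out of scope
  }
  events
}

#' Enumerate alternative-splicing events from gene models
#'
#' Compares every pair of transcripts within each gene and classifies local
#' differences into the seven event types (SE, IR, A5SS, A3SS, MXE, AFE,
#' ALE), attaching the inclusion- and exclusion-evidence junction ids.
#' Duplicate events (same type and defining intervals) found in several
#' transcript pairs are merged. For AFE/ALE the inclusion variant is the one
#' from the first-listed transcript of the pair; for MXE it is the
#' genomically upstream exon; for A5SS/A3SS the longer (more exonic)
#' variant; for IR the retention isoform, whose evidence is boundary-spanning
#' genome reads rather than junctions (`b1`, `b2` carry the two exon-intron
#' boundaries).
#'
#' @param genes named list of `gene_model`.
#' @return data.frame of class `as_events`, one row per event.
#' @export
enumerate_events <- function(genes) {
  rows <- list()
  for (gm in genes) {
    tids <- names(gm$transcripts)
    if (length(tids) < 2L) next
    for (i in seq_len(length(tids) - 1L)) {
      for (j in (i + 1L):length(tids)) {
        evs <- classify_pair(gm, gm$transcripts[[tids[i]]],
                             gm$transcripts[[tids[j]]])
        rows <- c(rows, evs)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(event_id = character(0), type = character(0),
                      gene_id = character(0), contig = character(0),
                      strand = character(0), alt_start = integer(0),
                      alt_end = integer(0), alt2_start = integer(0),
                      alt2_end = integer(0), inc_junctions = character(0),
                      exc_junctions = character(0), n_inc_junctions = integer(0),
                      n_exc_junctions = integer(0), b1 = integer(0),
                      b2 = integer(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    # canonical key: unordered pair of defining intervals
    key <- vapply(seq_len(nrow(out)), function(i) paste(
      out$gene_id[i], out$type[i],
      paste(sort(c(out$alt_start[i], out$alt_end[i],
                   out$alt2_start[i], out$alt2_end[i])), collapse = "_")),
      character(1))
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$gene_id, out$type, out$alt_start), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("as_events", "data.frame")
  out
}

# reads spanning a genomic boundary with >= min_overhang nt on each side,
# subject to the distinct-offset independence rule
boundary_read_count <- function(galn, contig, b, read_len, min_overhang,
                                min_independent) {
  sel <- galn$target == contig &
    galn$start <= b - min_overhang &
    galn$start + read_len >= b + min_overhang
  starts <- galn$start[sel]
  if (length(unique(starts)) < min_independent) return(0L)
  length(starts)
}

#' Attach read counts to events for one sample
#'
#' Inclusion and exclusion read counts are sums of junction counts over the
#' event's evidence sets; only junctions reported by [count_junctions()]
#' (covered by enough independent reads) contribute. IR retention evidence is
#' counted from genome alignments spanning either exon-intron boundary with
#' at least `min_overhang` nt on each side, under the same independence rule
#' applied per boundary.
#'
#' @param events from [enumerate_events()].
#' @param counts from [count_junctions()].
#' @param alignments from [align_reads()] (needed for IR; may be NULL when no
#'   IR events are present).
#' @param sample sample label.
#' @param read_len read length (IR boundary windows).
#' @param min_overhang,min_independent as in [count_junctions()].
#' @return data.frame (event_id, sample, inclusion_reads, exclusion_reads).
#' @export
quantify_events <- function(events, counts, alignments = NULL, sample,
                            read_len, min_overhang = 6L, min_independent = 2L) {
  reported <- counts[counts$reported, , drop = FALSE]
  cmap <- setNames(reported$total, reported$junction_id)
  jsum <- function(ids) {
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0L) return(0L)
    sum(cmap[ids], na.rm = TRUE)
  }
  galn <- if (!is.null(alignments))
    alignments[alignments$target_type == "genome", , drop = FALSE]
  else NULL
  inc <- integer(nrow(events)); exc <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$type == "IR") {
      if (is.null(galn)) stop("IR events require genome alignments")
      inc[i] <- boundary_read_count(galn, ev$contig, ev$b1, read_len,
                                    min_overhang, min_independent) +
        boundary_read_count(galn, ev$contig, ev$b2, read_len,
                            min_overhang, min_independent)
    } else {
      inc[i] <- jsum(strsplit(ev$inc_junctions, ",")[[1L]])
    }
    exc[i] <- jsum(strsplit(ev$exc_junctions, ",")[[1L]])
  }
  data.frame(event_id = events$event_id, sample = sample,
             inclusion_reads = inc, exclusion_reads = exc,
             stringsAsFactors = FALSE)
}

#' Percent spliced-in from junction counts
#'
#' PSI is the junction-normalized inclusion fraction
#' `(inc/n_inc) / (inc/n_inc + exc/n_exc)`: inclusion evidence of a cassette
#' exon is spread over two junctions while exclusion has one, so raw counts
#' are divided by the number of supporting junctions before forming the
#' ratio. Undefined (NA) when both normalized terms are zero.
#'
#' @param inclusion,exclusion read counts (vectors).
#' @param n_inc_junctions,n_exc_junctions junction multiplicities (>= 1).
#' @return numeric vector in `[0, 1]`, NA where undefined.
#' @export
compute_psi <- function(inclusion, exclusion, n_inc_junctions, n_exc_junctions) {
  if (any(n_inc_junctions < 1L) || any(n_exc_junctions < 1L))
    stop("junction multiplicities must be >= 1")
  if (any(inclusion < 0) || any(exclusion < 0)) stop("counts must be >= 0")
  ni <- inclusion / n_inc_junctions
  ne <- exclusion / n_exc_junctions
  ifelse(ni + ne == 0, NA_real_, ni / (ni + ne))
}
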