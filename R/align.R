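# Hamming-distance read assignment to genome and junction-library targets.
#
# Placements are found by pigeonhole seeding: a read allowed up to k
# mismatches is cut into k+1 disjoint seed segments, at least one of which
# must match its target exactly, so an exact-k-mer index over the targets
# enumerates every candidate placement; candidates are then verified by a
# direct base-by-base comparison. Both genome strands are searched; junction
# sequences are sense-oriented and searched as given.

#' Build the alignment target index
#'
#' @param genome `genome_seq`.
#' @param lib `junction_library` (may have zero rows).
#' @param read_len read length the index is built for.
#' @param max_mismatches mismatch allowance (determines seed length).
#' @return opaque index object for [align_reads()].
#' @export
build_align_index <- function(genome, lib, read_len, max_mismatches = 3L) {
  tnames <- character(0); ttypes <- character(0); tstrands <- character(0)
  tseqs <- character(0)
  for (ctg in names(genome)) {
    tnames <- c(tnames, ctg, ctg)
    ttypes <- c(ttypes, "genome", "genome")
    tstrands <- c(tstrands, "+", "-")
    tseqs <- c(tseqs, genome[[ctg]], revcomp(genome[[ctg]]))
  }
  if (nrow(lib) > 0L) {
    keep <- nchar(lib$seq) >= read_len
    if (any(keep)) {
      tnames <- c(tnames, lib$junction_id[keep])
      ttypes <- c(ttypes, rep("junction", sum(keep)))
      tstrands <- c(tstrands, rep("+", sum(keep)))
      tseqs <- c(tseqs, lib$seq[keep])
    }
  }
  lens <- nchar(tseqs)
  # concatenate with '#' separators so no spurious cross-target k-mers match
  concat <- paste(tseqs, collapse = "#")
  tstart <- cumsum(c(1L, head(lens + 1L, -1L)))   # 1-based start of each target
  tend <- tstart + lens - 1L
  k <- as.integer(floor(read_len / (max_mismatches + 1L)))
  if (k < 4L) stop("read too short for this mismatch allowance")
  N <- nchar(concat)
  kmers <- substring(concat, 1:(N - k + 1L), k:N)
  ok <- !grepl("#", kmers, fixed = TRUE)
  idx <- split(which(ok), kmers[ok])
  env <- list2env(idx, hash = TRUE, size = length(idx))
  left_len <- setNames(lib$left_len, lib$junction_id)
  list(concat = concat, craw = charToRaw(concat), env = env, k = k,
       read_len = as.integer(read_len), max_mismatches = as.integer(max_mismatches),
       tnames = tnames, ttypes = ttypes, tstrands = tstrands,
       tstart = tstart, tend = tend, tlens = lens, left_len = left_len)
}

# all verified placements of one read; returns data.frame
placements_one <- function(rseq, index) {
  L <- index$read_len; k <- index$k; mmax <- index$max_mismatches
  s <- mmax + 1L
  offs <- (0:(s - 1L)) * k
  cand <- integer(0)
  for (o in offs) {
    hit <- index$env[[substr(rseq, o + 1L, o + k)]]
    if (!is.null(hit)) cand <- c(cand, hit - o)
  }
  cand <- unique(cand)
  cand <- cand[cand >= 1L & cand + L - 1L <= nchar(index$concat)]
  if (length(cand) == 0L) return(NULL)
  ti <- findInterval(cand, index$tstart)
  inb <- cand + L - 1L <= index$tend[ti]
  cand <- cand[inb]; ti <- ti[inb]
  if (length(cand) == 0L) return(NULL)
  rraw <- charToRaw(rseq)
  mism <- vapply(cand, function(g)
    sum(index$craw[g:(g + L - 1L)] != rraw), integer(1))
  keep <- mism <= mmax
  cand <- cand[keep]; ti <- ti[keep]; mism <- mism[keep]
  if (length(cand) == 0L) return(NULL)
  lstart <- cand - index$tstart[ti]            # 0-based within target
  type <- index$ttypes[ti]
  target <- index$tnames[ti]
  strand <- index$tstrands[ti]
  start <- lstart
  overhang <- rep(NA_integer_, length(cand))
  # junction placements must actually span the junction point
  if (any(type == "junction")) {
    ji <- which(type == "junction")
    ll <- unname(index$left_len[target[ji]])
    left <- ll - lstart[ji]
    right <- lstart[ji] + L - ll
    overhang[ji] <- pmin(left, right)
    drop <- ji[left < 1L | right < 1L]
    if (length(drop) > 0L) {
      keep <- setdiff(seq_along(cand), drop)
      if (length(keep) == 0L) return(NULL)
      type <- type[keep]; target <- target[keep]; strand <- strand[keep]
      start <- start[keep]; mism <- mism[keep]; overhang <- overhang[keep]
      lstart <- lstart[keep]; ti <- ti[keep]
    }
  }
  # minus-strand genome placements: report plus-strand leftmost coordinate
  gi <- which(type == "genome" & strand == "-")
  if (length(gi) > 0L) start[gi] <- index$tlens[ti[gi]] - lstart[gi] - L
  data.frame(target_type = type, target = target, start = start,
             strand = strand, mismatches = mism, overhang = overhang,
             stringsAsFactors = FALSE)
}

#' Assign reads to genome and junction targets
#'
#' Enumerates every placement with at most `max_mismatches` mismatches over
#' both genome strands and the sense-oriented junction library. A read is
#' kept iff exactly one placement attains the minimum mismatch count;
#' ambiguous and unplaced reads are dropped and tallied in the summary
#' attribute. Junction placements must span the junction point (at least 1 nt
#' on each side) to count as junction evidence.
#'
#' @param reads named character vector (read_id -> sequence, ACGTN).
#' @param index from [build_align_index()], or NULL to build from
#'   `genome`/`lib`.
#' @param genome,lib used when `index` is NULL.
#' @param max_mismatches mismatch allowance (default 3).
#' @return data.frame of unique alignments (read_id, target_type, target,
#'   start, strand, mismatches, overhang) with attribute `summary`.
#' @export
align_reads <- function(reads, genome = NULL, lib = NULL, max_mismatches = 3L,
                        index = NULL) {
  if (any(grepl("[^ACGTN]", reads))) stop("reads contain non-ACGTN characters")
  L <- unique(nchar(reads))
  if (length(L) != 1L) stop("reads must have uniform length")
  if (is.null(index)) {
    index <- build_align_index(genome, lib, L, max_mismatches)
  }
  if (index$read_len != L) stop("index was built for a different read length")
  n <- length(reads)
  out <- vector("list", n)
  n_unique <- 0L; n_ambig <- 0L; n_unal <- 0L
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  for (i in seq_len(n)) {
    pl <- placements_one(reads[[i]], index)
    if (is.null(pl)) { n_unal <- n_unal + 1L; next }
    best <- min(pl$mismatches)
    at_best <- which(pl$mismatches == best)
    if (length(at_best) != 1L) { n_ambig <- n_ambig + 1L; next }
    n_unique <- n_unique + 1L
    out[[i]] <- cbind(read_id = ids[i], pl[at_best, , drop = FALSE])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(read_id = character(0), target_type = character(0),
                      target = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      overhang = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "summary") <- c(unique = n_unique, ambiguous = n_ambig,
                            unaligned = n_unal, total = n)
  res
}

#' Count junction-supporting reads
#'
#' Junction alignments with overhang of at least `min_overhang` nt are
#' aggregated per junction; "independent" reads are those at distinct start
#' offsets on the junction sequence (a guard against duplicate stacks).
#' Junctions are reported when covered by at least `min_independent`
#' independent reads.
#'
#' @param alignments data.frame from [align_reads()].
#' @param min_overhang minimum two-sided overhang in nt (default 6).
#' @param min_independent minimum distinct-offset reads (default 2).
#' @return data.frame (junction_id, total, independent, reported).
#' @export
count_junctions <- function(alignments, min_overhang = 6L, min_independent = 2L) {
  j <- alignments[alignments$target_type == "junction" &
                    !is.na(alignments$overhang) &
                    alignments$overhang >= min_overhang, , drop = FALSE]
  if (nrow(j) == 0L) {
    return(data.frame(junction_id = character(0), total = integer(0),
                      independent = integer(0), reported = logical(0),
                      stringsAsFactors = FALSE))
  }
  tot <- tapply(j$start, j$target, length)
  ind <- tapply(j$start, j$target, function(x) length(unique(x)))
  out <- data.frame(junction_id = names(tot), total = as.integer(tot),
                    independent = as.integer(ind),
                    stringsAsFactors = FALSE)
  out <- out[order(out$junction_id), , drop = FALSE]
  out$reported <- out$independent >= min_independent
  rownames(out) <- NULL
  out
}
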