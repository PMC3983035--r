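# Positional motif maps around cassette exons: per-position mean counts of
# the RNA-binding consensus (ACUAAU/ACUAAC by default) over anchored region
# frames, resampled control confidence bands, and the upstream-window
# enrichment test near the 3' splice site (where branchpoints sit, typically
# 18-35 nt upstream).

QKI_CORE_MOTIFS <- c("ACUAAU", "ACUAAC")
QKI_HALF_SITES <- c("UAAU", "UAAC")

#' Scan a sequence for exact motif matches
#'
#' Exact fixed-length matching on the given (pre-mRNA sense) sequence;
#' overlapping matches are allowed. RNA- and DNA-space input and motifs are
#' both accepted (U and T are equivalent).
#'
#' @param sequence a single character string over ACGTUN.
#' @param motifs character vector of motifs (default the ACUAAY consensus
#'   pair ACUAAU/ACUAAC).
#' @return sorted integer vector of 1-based match start positions.
#' @export
scan_motif <- function(sequence, motifs = QKI_CORE_MOTIFS) {
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  hits <- integer(0)
  for (m in unique(chartr("U", "T", toupper(motifs)))) {
    L <- nchar(m)
    if (n < L) next
    starts <- 1:(n - L + 1L)
    hits <- c(hits, starts[substring(s, starts, starts + L - 1L) == m])
  }
  sort(hits)
}

# locate the cassette exon of an SE event inside its gene model and return
# the sense-strand sequences of the five elements (upstream exon, upstream
# intron, cassette, downstream intron, downstream exon); "upstream" is in
# transcription direction. NULL if the exon is terminal in every transcript.
se_element_seqs <- function(ev, genes, genome) {
  gm <- genes[[ev$gene_id]]
  for (ex in gm$transcripts) {
    i <- which(ex$start == ev$alt_start & ex$end == ev$alt_end)
    if (length(i) == 1L && i > 1L && i < nrow(ex)) {
      gl <- list(exon_prev = c(ex$start[i - 1L], ex$end[i - 1L]),
                 intron_prev = c(ex$end[i - 1L], ex$start[i]),
                 cassette = c(ex$start[i], ex$end[i]),
                 intron_next = c(ex$end[i], ex$start[i + 1L]),
                 exon_next = c(ex$start[i + 1L], ex$end[i + 1L]))
      seqs <- lapply(gl, function(iv)
        exon_sense_seq(genome, gm$contig, iv[1], iv[2], gm$strand))
      if (gm$strand == "+") {
        names(seqs) <- c("exon_up", "intron_up", "cassette", "intron_dn", "exon_dn")
      } else {
        seqs <- seqs[c("exon_next", "intron_next", "cassette", "intron_prev", "exon_prev")]
        names(seqs) <- c("exon_up", "intron_up", "cassette", "intron_dn", "exon_dn")
      }
      return(seqs)
    }
  }
  NULL
}

# fixed coordinate frame of the profile
profile_frame <- function(U, I, E) {
  I5 <- as.integer(floor(I / 2)); I3 <- as.integer(ceiling(I / 2))
  frames <- list(
    exon_up      = data.frame(region = "exon_up", position = 1:U,
                              offset = -(U:1)),          # rel. upstream 5'ss
    intron_up_5p = data.frame(region = "intron_up_5p", position = 1:I5,
                              offset = 1:I5),            # rel. upstream 5'ss
    intron_up_3p = data.frame(region = "intron_up_3p", position = 1:I3,
                              offset = -(I3:1)),         # rel. cassette 3'ss
    cassette     = data.frame(region = "cassette", position = 1:E,
                              offset = 1:E),             # exon bin index
    intron_dn_5p = data.frame(region = "intron_dn_5p", position = 1:I5,
                              offset = 1:I5),            # rel. cassette 5'ss
    intron_dn_3p = data.frame(region = "intron_dn_3p", position = 1:I3,
                              offset = -(I3:1)),         # rel. downstream 3'ss
    exon_dn      = data.frame(region = "exon_dn", position = 1:U,
                              offset = 1:U))             # rel. downstream 3'ss
  fr <- do.call(rbind, frames)
  rownames(fr) <- NULL
  fr
}

#' Per-event motif hit and coverage matrices over the profile frame
#'
#' For each SE event with flanking introns, the five sense-strand elements
#' are scanned for the motifs; hit start positions are mapped into anchored
#' frames (exon flanks of width `U`, intron halves anchored at the 5' and 3'
#' splice sites totalling `I` nt, and the cassette exon length-normalized to
#' `E` bins). Regions shorter than the frame leave positions uncovered;
#' uncovered positions are excluded from averaging. Events whose cassette
#' exon is terminal in every transcript are dropped.
#'
#' @param events data.frame with gene_id, alt_start, alt_end (SE events).
#' @param genes,genome annotation.
#' @param motifs motif set for [scan_motif()].
#' @param U,I,E frame geometry (defaults 50, 250, 50).
#' @return list(hits, cover, frame, event_id): matrices n_events x positions.
#' @export
event_motif_matrix <- function(events, genes, genome, motifs = QKI_CORE_MOTIFS,
                               U = 50L, I = 250L, E = 50L) {
  if (nrow(events) == 0L) stop("empty event set")
  fr <- profile_frame(U, I, E)
  P <- nrow(fr)
  I5 <- sum(fr$region == "intron_up_5p"); I3 <- sum(fr$region == "intron_up_3p")
  idx <- split(seq_len(P), fr$region)
  hits <- matrix(0, nrow(events), P)
  cover <- matrix(0, nrow(events), P)
  kept <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    el <- se_element_seqs(events[i, ], genes, genome)
    if (is.null(el)) next
    kept[i] <- TRUE
    hv <- numeric(P); cv <- numeric(P)
    # upstream exon: last U nt, right-aligned
    n <- nchar(el$exon_up); w <- min(U, n)
    cv[idx$exon_up[(U - w + 1L):U]] <- 1
    h <- scan_motif(el$exon_up, motifs)
    h <- h[h > n - w]                       # starts within the covered flank
    if (length(h)) for (p in h) {
      j <- idx$exon_up[U - (n - p)]
      hv[j] <- hv[j] + 1
    }
    # introns: first I5 nt left-aligned, last I3 right-aligned; short introns
    # are split in half to avoid double counting
    intron_fill <- function(seq, idx5, idx3) {
      n <- nchar(seq)
      w5 <- if (n >= I5 + I3) I5 else floor(n / 2)
      w3 <- if (n >= I5 + I3) I3 else n - w5
      if (w5 > 0) cv[idx5[1:w5]] <<- 1
      if (w3 > 0) cv[idx3[(I3 - w3 + 1L):I3]] <<- 1
      h <- scan_motif(seq, motifs)
      for (p in h) {
        if (p <= w5) { j <- idx5[p]; hv[j] <<- hv[j] + 1 }
        else if (p > n - w3) { j <- idx3[I3 - (n - p)]; hv[j] <<- hv[j] + 1 }
      }
    }
    intron_fill(el$intron_up, idx$intron_up_5p, idx$intron_up_3p)
    intron_fill(el$intron_dn, idx$intron_dn_5p, idx$intron_dn_3p)
    # cassette exon: length-normalized bins
    n <- nchar(el$cassette)
    cv[idx$cassette] <- 1
    for (p in scan_motif(el$cassette, motifs)) {
      b <- min(E, 1L + as.integer(floor((p - 1) / n * E)))
      j <- idx$cassette[b]
      hv[j] <- hv[j] + 1
    }
    # downstream exon: first U nt, left-aligned
    n <- nchar(el$exon_dn); w <- min(U, n)
    cv[idx$exon_dn[1:w]] <- 1
    h <- scan_motif(el$exon_dn, motifs)
    h <- h[h <= w]
    if (length(h)) for (p in h) {
      j <- idx$exon_dn[p]
      hv[j] <- hv[j] + 1
    }
    hits[i, ] <- hv; cover[i, ] <- cv
  }
  if (!any(kept)) stop("no event with flanking introns")
  list(hits = hits[kept, , drop = FALSE], cover = cover[kept, , drop = FALSE],
       frame = fr, event_id = events$event_id[kept])
}

profile_from_matrix <- function(mm) {
  cov <- colSums(mm$cover)
  mean <- ifelse(cov > 0, colSums(mm$hits) / pmax(cov, 1), NA_real_)
  data.frame(mm$frame, mean = mean, n_covered = cov, stringsAsFactors = FALSE)
}

smooth_profile <- function(prof, w = 20L) {
  sm <- rep(NA_real_, nrow(prof))
  for (r in unique(prof$region)) {
    i <- which(prof$region == r)
    if (r == "cassette") { sm[i] <- prof$mean[i]; next }  # bins stay unsmoothed
    x <- prof$mean[i]
    half <- floor(w / 2)
    sm[i] <- vapply(seq_along(x), function(k) {
      lo <- max(1L, k - half); hi <- min(length(x), k + half)
      mean(x[lo:hi], na.rm = TRUE)
    }, numeric(1))
  }
  sm
}

#' Positional motif map for activated / repressed / control exon sets
#'
#' @param sets named list of SE-event data.frames (e.g. activated, repressed,
#'   control).
#' @param genes,genome annotation.
#' @param motifs motif set (default ACUAAU/ACUAAC).
#' @param U,I,E frame geometry.
#' @param smooth_w centered sliding-window width in nt for the smoothed
#'   track (default 20; cassette bins are not smoothed).
#' @return long data.frame (set, region, position, offset, mean, mean_smooth,
#'   n_covered).
#' @export
build_motif_map <- function(sets, genes, genome, motifs = QKI_CORE_MOTIFS,
                            U = 50L, I = 250L, E = 50L, smooth_w = 20L) {
  out <- list()
  for (nm in names(sets)) {
    mm <- event_motif_matrix(sets[[nm]], genes, genome, motifs, U, I, E)
    prof <- profile_from_matrix(mm)
    prof$mean_smooth <- smooth_profile(prof, smooth_w)
    out[[nm]] <- cbind(set = nm, prof)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resampled control confidence band for the motif profile
#'
#' Draws `set_size` events from the control pool without replacement
#' `n_resamples` times and takes empirical quantiles of the per-position
#' means at the requested level. When `n_resamples` is too small to resolve
#' the requested extreme quantiles, a warning is issued and the achievable
#' level `1 - 2/n_resamples` is used instead (reported in the output).
#'
#' @param control_events control-pool SE events (data.frame).
#' @param genes,genome annotation.
#' @param set_size size of the resampled sets (the size of the tested set).
#' @param n_resamples number of resamples (default 10000).
#' @param level two-sided confidence level (default 0.999999).
#' @param seed integer seed.
#' @param motifs,U,I,E as in [event_motif_matrix()].
#' @return data.frame (region, position, offset, band_low, band_high) with
#'   attribute `level_used`.
#' @export
control_confidence_band <- function(control_events, genes, genome, set_size,
                                    n_resamples = 10000L, level = 0.999999,
                                    seed, motifs = QKI_CORE_MOTIFS,
                                    U = 50L, I = 250L, E = 50L) {
  mm <- event_motif_matrix(control_events, genes, genome, motifs, U, I, E)
  n_pool <- nrow(mm$hits)
  if (n_pool < set_size) stop("control pool smaller than set_size")
  level_used <- level
  if (level > 0 && n_resamples < 2 / (1 - level)) {
    level_used <- 1 - 2 / n_resamples
    warning(sprintf(paste0("n_resamples = %d cannot resolve the %g confidence",
                           " level; reporting the achievable %g level"),
                    n_resamples, level, level_used))
  }
  set.seed(seed)
  P <- ncol(mm$hits)
  means <- matrix(NA_real_, n_resamples, P)
  for (r in seq_len(n_resamples)) {
    pick <- sample.int(n_pool, set_size)
    cov <- colSums(mm$cover[pick, , drop = FALSE])
    means[r, ] <- ifelse(cov > 0, colSums(mm$hits[pick, , drop = FALSE]) /
                           pmax(cov, 1), NA_real_)
  }
  alpha <- (1 - level_used) / 2
  lo <- apply(means, 2, quantile, probs = alpha, na.rm = TRUE, names = FALSE)
  hi <- apply(means, 2, quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
  out <- data.frame(mm$frame, band_low = lo, band_high = hi,
                    stringsAsFactors = FALSE)
  attr(out, "level_used") <- level_used
  out
}

# motif counts per event in an offset window of the upstream intron,
# anchored at the 3' splice site (offset -1 = last intron base)
upstream_window_counts <- function(events, genes, genome, motifs, window) {
  counts <- rep(NA_real_, nrow(events))
  truncated <- 0L
  for (i in seq_len(nrow(events))) {
    el <- se_element_seqs(events[i, ], genes, genome)
    if (is.null(el)) next
    n <- nchar(el$intron_up)
    if (n < -window[1]) truncated <- truncated + 1L
    h <- scan_motif(el$intron_up, motifs)
    off <- h - n - 1L
    counts[i] <- sum(off >= window[1] & off <= window[2])
  }
  list(counts = counts[!is.na(counts)], truncated = truncated)
}

#' Motif enrichment in the upstream branchpoint window
#'
#' Compares the mean motif count in a window upstream of the 3' splice site
#' (default [-40, -1] nt, covering the branchpoint region) between a
#' regulated exon set and a control pool. Significance is assessed by
#' drawing size-matched control subsets: p is the (add-one corrected)
#' fraction of resamples whose ratio to the control-pool mean reaches the
#' observed ratio.
#'
#' @param repressed_events,control_events SE-event data.frames.
#' @param genes,genome annotation.
#' @param window offset window relative to the 3'ss (default c(-40, -1)).
#' @param motifs motif set.
#' @param n_perm number of resamples (default 10000).
#' @param seed integer seed.
#' @return list(density_ratio, p, mean_repressed, mean_control, window,
#'   n_truncated).
#' @export
upstream_window_enrichment <- function(repressed_events, control_events,
                                       genes, genome, window = c(-40L, -1L),
                                       motifs = QKI_CORE_MOTIFS,
                                       n_perm = 10000L, seed) {
  rep_c <- upstream_window_counts(repressed_events, genes, genome, motifs, window)
  ctl_c <- upstream_window_counts(control_events, genes, genome, motifs, window)
  m_rep <- mean(rep_c$counts); m_ctl <- mean(ctl_c$counts)
  ratio <- if (m_ctl == 0) Inf else m_rep / m_ctl
  set.seed(seed)
  k <- length(rep_c$counts); pool <- ctl_c$counts
  null_ratio <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    m <- mean(pool[sample.int(length(pool), k, replace = length(pool) < k)])
    null_ratio[r] <- if (m_ctl == 0) {
      if (m > 0) Inf else 0
    } else m / m_ctl
  }
  p <- (1 + sum(null_ratio >= ratio)) / (n_perm + 1)
  list(density_ratio = ratio, p = p, mean_repressed = m_rep,
       mean_control = m_ctl, window = window,
       n_truncated = rep_c$truncated + ctl_c$truncated)
}
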