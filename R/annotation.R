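#' @importFrom stats p.adjust dhyper quantile setNames
#' @importFrom utils write.table read.table head
NULL

# ---- genome sequences --------------------------------------------------------

#' Read a genome from a FASTA file
#'
#' Returns a named character vector (one element per record, names taken from
#' the first word of each header). Sequences are uppercased and U is mapped to
#' T so RNA-space FASTA is accepted; any other non-ACGTN character is an
#' error.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector of class `genome_seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_genome(seqs)
}

validate_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("genome has no sequences")
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty sequence for contig(s): ",
                               paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in contig(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "genome_seq")
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Extract a genome subsequence
#'
#' Coordinates are 0-based half-open. Out-of-range access is an error rather
#' than silently clipped.
#' @param genome `genome_seq`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @export
genome_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, contig, len))
  }
  substr(genome[[contig]], start + 1L, end)
}

#' Reverse complement of DNA strings
#' @param x character vector over ACGTN.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- gene models -------------------------------------------------------------

#' Construct a gene model
#'
#' A gene model is a gene with one or more transcripts, each an ordered set of
#' exons on a single contig and strand. Exon coordinates are 0-based
#' half-open; exons within a transcript must be sorted, non-overlapping and
#' non-empty.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param transcripts named list; each element a data.frame with integer
#'   columns `start`, `end`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, transcripts) {
  gm <- structure(
    list(gene_id = gene_id, contig = contig, strand = strand,
         transcripts = transcripts),
    class = "gene_model")
  validate_gene_model(gm)
}

validate_gene_model <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (!gm$strand %in% c("+", "-")) stop("strand must be '+' or '-' for ", gm$gene_id)
  if (length(gm$transcripts) < 1L) stop("gene ", gm$gene_id, " has no transcripts")
  if (is.null(names(gm$transcripts)) || any(!nzchar(names(gm$transcripts))))
    stop("transcripts must be named for ", gm$gene_id)
  for (tid in names(gm$transcripts)) {
    ex <- gm$transcripts[[tid]]
    if (nrow(ex) < 1L) stop("transcript ", tid, " has no exons")
    if (any(ex$start < 0) || any(ex$end <= ex$start))
      stop("invalid exon interval in transcript ", tid)
    if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1L)
      stop("exons of transcript ", tid, " are not sorted by start")
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tid)
  }
  gm
}

#' Check gene models against a genome
#'
#' Verifies every exon lies within its contig.
#' @param genes list of `gene_model`.
#' @param genome `genome_seq`.
#' @export
validate_models <- function(genes, genome) {
  for (gm in genes) {
    if (!gm$contig %in% names(genome)) stop("unknown contig in ", gm$gene_id)
    len <- nchar(genome[[gm$contig]])
    for (ex in gm$transcripts) {
      if (any(ex$end > len)) stop("exon out of genome bounds in ", gm$gene_id)
    }
  }
  invisible(genes)
}

#' Read gene models from a GTF file
#'
#' Only `exon` features are consumed. 1-based closed GTF coordinates are
#' converted to the package's 0-based half-open convention. Exons are grouped
#' by `transcript_id` and transcripts by `gene_id`; a transcript with exons on
#' more than one strand or contig is an error, as is an exon record without a
#' `transcript_id`.
#'
#' @param path path to a GTF file (Ensembl dialect attributes).
#' @return named list of `gene_model`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gid <- as.character(md$gene_id)
  if (any(is.na(tid)) || any(!nzchar(tid)))
    stop("exon feature without transcript_id in ", path)
  if (any(is.na(gid)) || any(!nzchar(gid)))
    stop("exon feature without gene_id in ", path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid, transcript_id = tid,
    stringsAsFactors = FALSE)
  genes <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    if (length(unique(sub$strand)) != 1L)
      stop("mixed strands within gene ", g)
    if (length(unique(sub$contig)) != 1L)
      stop("mixed contigs within gene ", g)
    if (any(sub$strand == "*")) stop("exon without strand in gene ", g)
    txs <- list()
    for (t in unique(sub$transcript_id)) {
      ex <- sub[sub$transcript_id == t, c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      txs[[t]] <- ex
    }
    genes[[g]] <- gene_model(g, sub$contig[1L], sub$strand[1L], txs)
  }
  genes
}

#' Write gene models to a GTF file
#' @param genes named list of `gene_model`.
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (gm in genes) {
    for (tid in names(gm$transcripts)) {
      ex <- gm$transcripts[[tid]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gm$gene_id, tid)
      lines <- c(lines, sprintf("%s\tdasmap\texon\t%d\t%d\t.\t%s\t.\t%s",
                                gm$contig, ex$start + 1L, ex$end, gm$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- junction library --------------------------------------------------------

#' Exonic flank length per junction side
#'
#' A read of length `read_len` aligned across a junction with at least
#' `min_overhang` nt on the far side can extend at most
#' `read_len - min_overhang` nt into either flank, so that is the flank
#' length used when building junction library sequences (44 nt for 50-nt
#' reads, 69 nt for 75-nt reads at the default 6-nt overhang).
#'
#' @param read_len read length in nt.
#' @param min_overhang minimum alignment overhang in nt (default 6).
#' @return flank length in nt.
#' @export
junction_flank_length <- function(read_len, min_overhang = 6L) {
  if (min_overhang < 1L) stop("min_overhang must be >= 1")
  if (read_len <= min_overhang) stop("read_len must exceed min_overhang")
  as.integer(read_len - min_overhang)
}

#' Junction identifier
#'
#' Donor and acceptor are the genomic coordinates of the splice points
#' (0-based; for a + strand gene the donor is the exclusive end of the
#' upstream exon and the acceptor the start of the downstream exon; on the -
#' strand the roles are mirrored).
#' @keywords internal
junction_id <- function(gene_id, contig, donor, acceptor, strand) {
  paste(gene_id, contig, donor, acceptor, strand, sep = "|")
}

# sense-strand sequence of an exon interval
exon_sense_seq <- function(genome, contig, start, end, strand) {
  s <- genome_subseq(genome, contig, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Build the splice-junction library for a set of genes
#'
#' Joins every exon of a gene with all exons strictly downstream of it in
#' transcription direction, pooling exons over all transcripts of the gene
#' and deduplicating by (donor, acceptor). Each entry carries
#' `flank_len = read_len - min_overhang` nt of exonic sequence per side
#' (truncated, and flagged, when an exon is shorter than the flank); the
#' stored sequence reads 5'->3' on the mRNA sense strand.
#'
#' @param genes named list of `gene_model`.
#' @param genome `genome_seq`.
#' @param read_len design read length.
#' @param min_overhang minimum alignment overhang (default 6).
#' @return data.frame of class `junction_library` with one row per junction.
#' @export
build_junction_library <- function(genes, genome, read_len, min_overhang = 6L) {
  flank <- junction_flank_length(read_len, min_overhang)
  validate_models(genes, genome)
  rows <- vector("list", length(genes))
  k <- 0L
  for (gm in genes) {
    ex <- unique(do.call(rbind, unname(gm$transcripts)))
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2L) next
    pairs <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        # strictly downstream in genomic order, non-overlapping
        if (ex$start[j] >= ex$end[i]) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
    if (length(pairs) == 0L) next
    res <- lapply(pairs, function(p) {
      # up = transcriptionally upstream exon
      if (gm$strand == "+") { up <- p[1L]; dn <- p[2L] } else { up <- p[2L]; dn <- p[1L] }
      up_len <- ex$end[up] - ex$start[up]
      dn_len <- ex$end[dn] - ex$start[dn]
      left_len  <- min(flank, up_len)
      right_len <- min(flank, dn_len)
      up_seq <- exon_sense_seq(genome, gm$contig, ex$start[up], ex$end[up], gm$strand)
      dn_seq <- exon_sense_seq(genome, gm$contig, ex$start[dn], ex$end[dn], gm$strand)
      left  <- substr(up_seq, up_len - left_len + 1L, up_len)
      right <- substr(dn_seq, 1L, right_len)
      if (gm$strand == "+") { donor <- ex$end[up]; acceptor <- ex$start[dn] }
      else                  { donor <- ex$start[up]; acceptor <- ex$end[dn] }
      data.frame(
        junction_id = junction_id(gm$gene_id, gm$contig, donor, acceptor, gm$strand),
        gene_id = gm$gene_id, contig = gm$contig, strand = gm$strand,
        donor = donor, acceptor = acceptor,
        flank_len = flank, left_len = left_len, right_len = right_len,
        seq = paste0(left, right),
        truncated = (left_len < flank || right_len < flank),
        stringsAsFactors = FALSE)
    })
    k <- k + 1L
    rows[[k]] <- do.call(rbind, res)
  }
  lib <- if (k == 0L) {
    data.frame(junction_id = character(0), gene_id = character(0),
               contig = character(0), strand = character(0),
               donor = integer(0), acceptor = integer(0),
               flank_len = integer(0), left_len = integer(0),
               right_len = integer(0), seq = character(0),
               truncated = logical(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows[seq_len(k)])
  }
  lib <- lib[!duplicated(lib$junction_id), , drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("junction_library", "data.frame")
  lib
}

#' Export a junction library as FASTA plus a TSV index
#' @param lib `junction_library`.
#' @param fasta_path,tsv_path output paths.
#' @export
write_junction_library <- function(lib, fasta_path, tsv_path) {
  ss <- Biostrings::DNAStringSet(setNames(lib$seq, lib$junction_id))
  Biostrings::writeXStringSet(ss, filepath = fasta_path)
  write.table(lib[, setdiff(names(lib), "seq")], tsv_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}
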