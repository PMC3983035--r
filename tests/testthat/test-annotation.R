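test_that("FASTA reading normalizes case and alphabet and rejects bad input", {
  f <- write_temp_fasta(c(">c1", "ACGT"))
  expect_equal(unclass(read_fasta(f))[["c1"]], "ACGT")
  f <- write_temp_fasta(c(">c1 description text", "acgu"))
  g <- read_fasta(f)
  expect_equal(names(g), "c1")
  expect_equal(g[["c1"]], "ACGT")
  expect_error(read_fasta(write_temp_fasta(c(">c1", "AC", ">c1", "GT"))),
               "duplicate contig")
  expect_error(read_fasta(write_temp_fasta(c(">c1", "ACXT"))), "non-ACGTN")
  f <- write_temp_fasta(c(">c1", "ACGTNNAC"))
  expect_equal(read_fasta(f)[["c1"]], "ACGTNNAC")
})

test_that("FASTA round-trips through write_fasta", {
  g <- dasmap:::validate_genome(c(a = "ACGTACGTAA", b = "TTTTGGGGCC"))
  f <- tempfile(fileext = ".fa")
  write_fasta(g, f)
  expect_equal(unclass(read_fasta(f)), unclass(g))
})

test_that("genome_subseq enforces bounds", {
  g <- dasmap:::validate_genome(c(c1 = "ACGTACGT"))
  expect_equal(genome_subseq(g, "c1", 0, 4), "ACGT")
  expect_equal(genome_subseq(g, "c1", 4, 8), "ACGT")
  expect_error(genome_subseq(g, "c1", 4, 9), "out of bounds")
  expect_error(genome_subseq(g, "c1", -1, 4), "out of bounds")
  expect_error(genome_subseq(g, "c2", 0, 4), "unknown contig")
})

test_that("GTF reading converts coordinates, filters features, validates strands", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tsrc\texon\t11\t30\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tsrc\tCDS\t15\t25\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tsrc\texon\t61\t85\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'), gtf)
  genes <- read_gtf(gtf)
  expect_length(genes, 1)
  ex <- genes$g1$transcripts$t1
  expect_equal(ex$start, c(10L, 60L))   # 1-based closed -> 0-based half-open
  expect_equal(ex$end, c(30L, 85L))
  expect_equal(nrow(ex), 2L)            # CDS line ignored

  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tsrc\texon\t11\t30\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tsrc\texon\t61\t85\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'), bad)
  expect_error(read_gtf(bad), "mixed strands")
})

test_that("gene models round-trip through write_gtf/read_gtf", {
  cfg <- sim_config(seed = 3, events_per_type = c(SE = 1, MXE = 1, ALE = 1))
  sim <- simulate_annotation(cfg)
  f <- tempfile(fileext = ".gtf")
  write_gtf(sim$genes, f)
  back <- read_gtf(f)
  expect_setequal(names(back), names(sim$genes))
  for (g in names(sim$genes)) {
    expect_equal(back[[g]]$strand, sim$genes[[g]]$strand)
    for (t in names(sim$genes[[g]]$transcripts)) {
      expect_equal(back[[g]]$transcripts[[t]], sim$genes[[g]]$transcripts[[t]])
    }
  }
})

test_that("junction flank length is read length minus the overhang", {
  expect_identical(junction_flank_length(50, 6), 44L)
  expect_identical(junction_flank_length(75, 6), 69L)
  expect_identical(junction_flank_length(7, 6), 1L)
  expect_error(junction_flank_length(6, 6), "exceed")
  expect_error(junction_flank_length(50, 0), ">= 1")
})

test_that("junction count for a single-transcript gene is C(n, 2)", {
  # exhaustive pair-enumeration oracle over n = 2..8 non-overlapping exons
  set.seed(42)
  for (n in 2:8) {
    starts <- cumsum(c(20L, rep(40L, n - 1L)))
    ex <- data.frame(start = starts, end = starts + 20L)
    glen <- max(ex$end) + 50L
    genome <- dasmap:::validate_genome(c(c1 = paste(
      sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = "")))
    gm <- gene_model("g1", "c1", "+", list(t1 = ex))
    lib <- build_junction_library(list(g1 = gm), genome, read_len = 20,
                                  min_overhang = 6)
    oracle <- sum(outer(seq_len(n), seq_len(n),
                        function(i, j) j > i & ex$start[j] >= ex$end[i]))
    expect_equal(nrow(lib), choose(n, 2), info = paste("n =", n))
    expect_equal(nrow(lib), oracle)
  }
})

test_that("minus-strand junction sequence is the reverse complement of the
           plus-strand flank pair", {
  toy <- toy_two_exon("-")
  lib <- build_junction_library(list(gX = toy$gene), toy$genome,
                                read_len = 11, min_overhang = 6)
  expect_equal(nrow(lib), 1L)
  # manual: flank 5; on '-' the transcription-upstream (donor) exon is the
  # genomic right one; the junction sequence is revcomp(acceptor-exon 5'
  # flank + donor-exon 3' flank, both read on the plus strand)
  acc_flank <- genome_subseq(toy$genome, "c1", 25, 30)   # last 5 of [10,30)
  don_flank <- genome_subseq(toy$genome, "c1", 60, 65)   # first 5 of [60,85)
  expect_equal(lib$seq, revcomp(paste0(acc_flank, don_flank)))
  expect_equal(lib$donor, 60)
  expect_equal(lib$acceptor, 30)
})

test_that("plus and minus strand junctions carry genome substring pairs", {
  cfg <- sim_config(seed = 5, events_per_type = c(SE = 2, A5SS = 1))
  sim <- simulate_annotation(cfg)
  lib <- build_junction_library(sim$genes, sim$genome, 50)
  for (i in seq_len(nrow(lib))) {
    le <- lib$left_len[i]
    left <- substr(lib$seq[i], 1, le)
    right <- substr(lib$seq[i], le + 1, nchar(lib$seq[i]))
    ctg <- sim$genome[[lib$contig[i]]]
    if (lib$strand[i] == "+") {
      expect_true(grepl(left, ctg, fixed = TRUE))
      expect_true(grepl(right, ctg, fixed = TRUE))
    } else {
      expect_true(grepl(revcomp(left), ctg, fixed = TRUE))
      expect_true(grepl(revcomp(right), ctg, fixed = TRUE))
    }
  }
})

test_that("flank truncation flags short exons and never exceeds 2*flank", {
  genome <- dasmap:::validate_genome(c(c1 = strrep("ACGT", 100)))
  gm <- gene_model("g1", "c1", "+",
                   list(t1 = data.frame(start = c(0L, 50L, 200L),
                                        end = c(10L, 150L, 300L))))
  lib <- build_junction_library(list(g1 = gm), genome, read_len = 50)
  expect_true(all(nchar(lib$seq) <= 2L * lib$flank_len))
  short <- lib$donor == 10   # junctions leaving the 10-nt exon
  expect_true(all(lib$truncated[short]))
  expect_equal(lib$left_len[short], c(10L, 10L))
  expect_false(any(lib$truncated[!short] & lib$left_len[!short] < 44L &
                     lib$right_len[!short] < 44L))
})
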