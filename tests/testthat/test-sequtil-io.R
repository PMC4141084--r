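test_that("FASTQ records are decoded with Phred+33 qualities and U->T", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2 extra comment", "acgu", "+", "!!!!"), path)
  reads <- read_fastq(path)
  expect_equal(reads$id, c("r1", "r2"))
  expect_equal(reads$seq, c("ACGT", "ACGT"))
  expect_equal(reads$qual[[1]], rep(40L, 4))
  expect_equal(reads$qual[[2]], rep(0L, 4))
})

test_that("empty FASTQ yields an empty read table", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  expect_equal(nrow(read_fastq(path)), 0L)
})

test_that("FASTQ length mismatches are fatal and name the record", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@ok", "ACGT", "+", "IIII",
               "@bad1", "ACGTA", "+", "IIII"), path)
  expect_error(read_fastq(path), "bad1")
})

test_that("FASTQ ingest preserves record count and per-record length", {
  set.seed(301)
  seqs <- vapply(sample(10:23, 50, TRUE), random_seq, character(1))
  reads <- make_reads(seqs)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_file(reads, path)
  back <- read_fastq(path)
  expect_equal(nrow(back), 50L)
  expect_equal(nchar(back$seq), nchar(seqs))
  expect_equal(lengths(back$qual), nchar(seqs))
})

test_that("FASTA sequences are concatenated and normalized", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 description here", "ACGT", "ACGT", ">s2", "acgu"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs, c(s1 = "ACGTACGT", s2 = "ACGT"))
})

test_that("FASTA with invalid characters or no header is fatal", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACXT"), path)
  expect_error(read_fasta(path), "invalid character")
  path2 <- withr::local_tempfile(fileext = ".fa")
  writeLines("ACGTACGT", path2)
  expect_error(read_fasta(path2))
})

test_that("collapsed FASTA round-trips copy counts through _x headers", {
  collapsed <- data.frame(id = c("t1", "t2"), seq = c("ACGTACGTAC", "TTTTTTTTTT"),
                          count = c(7L, 1L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(collapsed, path)
  back <- read_collapsed_fasta(path)
  expect_equal(back$count, c(7L, 1L))
  expect_equal(back$id, c("t1", "t2"))
  # headers without the suffix default to count 1
  path2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">plain", "ACGTACGTAC"), path2)
  expect_equal(read_collapsed_fasta(path2)$count, 1L)
})

test_that("SAM output uses 1-based POS, flag 16 with revcomp SEQ, and XS", {
  genome <- c(c1 = "ACGTACGTAAACGTACGTAA")
  aln <- make_alignments("c1", start = 5L, len = 4L, strand = "+",
                         count = 7L, seq = "ACGT", id = "r1")
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, genome, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@SQ\tSN:c1\tLN:20$", lines)))
  rec <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[4]), 5L)
  expect_true("XS:i:7" %in% rec)

  neg <- make_alignments("c1", start = 1L, len = 4L, strand = "-",
                         count = 2L, seq = "ACGT", id = "r2")
  write_sam(neg, genome, path)
  rec <- strsplit(grep("^r2\t", readLines(path), value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[2]), 16L)
  expect_equal(rec[10], revcomp("ACGT"))

  write_sam(aln[0, ], genome, path)
  expect_true(all(startsWith(readLines(path), "@")))
})

test_that("SAM reading defaults missing XS to 1, skips unmapped, needs @SQ", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:c1\tLN:100",
               "r1\t0\tc1\t5\t255\t4M\t*\t0\t0\tACGT\t*\tXS:i:7",
               "r2\t0\tc1\t9\t255\t4M\t*\t0\t0\tGGGG\t*",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\tCCCC\t*"), path)
  aln <- read_alignments(path)
  expect_equal(aln$id, c("r1", "r2"))
  expect_equal(aln$start, c(5L, 9L))
  expect_equal(aln$count, c(7L, 1L))
  path2 <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\t0\tc1\t5\t255\t4M\t*\t0\t0\tACGT\t*", path2)
  expect_error(read_alignments(path2), "@SQ")
})

test_that("SAM round trip reproduces arbitrary alignment sets", {
  set.seed(302)
  genome <- c(chrA = random_seq(500), chrB = random_seq(300))
  for (trial in 1:5) {
    n <- sample(1:20, 1)
    chrom <- sample(names(genome), n, TRUE)
    len <- sample(10:23, n, TRUE)
    start <- vapply(seq_len(n), function(i)
      sample.int(nchar(genome[[chrom[i]]]) - len[i], 1), integer(1))
    aln <- data.frame(id = sprintf("t%d", 1:n), chrom = chrom, start = start,
                      end = start + len - 1L,
                      strand = sample(c("+", "-"), n, TRUE),
                      seq = vapply(len, random_seq, character(1)),
                      count = sample(1:50, n, TRUE), stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".sam")
    write_sam(aln, genome, path)
    back <- read_alignments(path)
    expect_equal(back, aln)
  }
})

test_that("written SAM agrees with Rsamtools' reading of the same records", {
  set.seed(303)
  genome <- c(c1 = random_seq(400))
  aln <- make_alignments("c1", start = c(11L, 101L, 201L), len = 21L,
                         strand = c("+", "-", "+"), count = c(9L, 4L, 1L))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, genome, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam),
                            param = Rsamtools::ScanBamParam(
                              what = c("pos", "flag"), tag = "XS"))[[1]]
  expect_setequal(res$pos, aln$start)
  expect_setequal(res$tag$XS, aln$count)
  expect_equal(sum(bitwAnd(res$flag, 16L) != 0L), sum(aln$strand == "-"))
  # and our own BAM reader recovers the records
  back <- read_alignments(bam)
  back <- back[order(back$start), ]
  rownames(back) <- NULL
  expect_equal(back[, c("chrom", "start", "end", "strand", "count")],
               aln[, c("chrom", "start", "end", "strand", "count")])
})
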