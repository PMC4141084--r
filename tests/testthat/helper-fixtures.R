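# Shared fixture builders; everything is generated in code at test time.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a read table as produced by read_fastq()
make_reads <- function(seqs, quals = NULL, ids = NULL) {
  ids <- ids %||% sprintf("r%d", seq_along(seqs))
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(l) rep(40L, l))
  data.frame(id = ids, seq = seqs, qual = I(quals), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fastq_file <- function(reads, path) {
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                    vapply(reads$qual, function(q)
                      rawToChar(as.raw(q + 33L)), character(1))), path)
  path
}

# a perfect stem-loop: mature + spacer + revcomp(mature); returns sequence
# and the 1-based star interval
make_stem_loop <- function(mature, spacer_len, spacer_base = "A") {
  spacer <- strrep(spacer_base, spacer_len)
  seq <- paste0(mature, spacer, plantmir::revcomp(mature))
  list(sequence = seq,
       mature = c(1L, nchar(mature)),
       star = c(nchar(mature) + spacer_len + 1L, nchar(seq)))
}

# a hand-built fold result from an explicit pair list (rows (i,j), 1-based)
fake_fold <- function(sequence_len, pair_rows) {
  pairs <- integer(sequence_len)
  if (length(pair_rows)) {
    pm <- do.call(rbind, pair_rows)
    pairs[pm[, 1L]] <- pm[, 2L]
    pairs[pm[, 2L]] <- pm[, 1L]
  }
  db <- rep(".", sequence_len)
  db[pairs > seq_len(sequence_len)] <- "("
  db[pairs > 0L & pairs < seq_len(sequence_len)] <- ")"
  structure(list(sequence = strrep("N", sequence_len), pairs = pairs,
                 dotbracket = paste(db, collapse = ""), energy = -10),
            class = "fold_result")
}

# alignment rows helper
make_alignments <- function(chrom, start, len, strand = "+", count = 1L,
                            seq = NULL, id = NULL) {
  n <- max(length(start), length(count))
  start <- rep_len(start, n); len <- rep_len(len, n)
  strand <- rep_len(strand, n); count <- rep_len(as.integer(count), n)
  data.frame(id = id %||% sprintf("a%d", seq_len(n)), chrom = chrom,
             start = start, end = start + len - 1L, strand = strand,
             seq = seq %||% vapply(len, random_seq, character(1)),
             count = count, stringsAsFactors = FALSE)
}

# small end-to-end simulation shared by pipeline/report tests
run_small_sim <- function(seed = 11L, n_hairpins = 5L, genome_len = 30000L,
                          reads_per_locus = 60L) {
  spec <- sim_spec(genome_len = genome_len, n_hairpins = n_hairpins,
                   span = c(100L, 160L), loop_len = 25L,
                   reads_per_locus = reads_per_locus, seed = seed)
  g <- make_genome(spec)
  reads <- simulate_reads(g$genome, g$truth, spec)
  pp <- preprocess_reads(reads)
  idx <- build_index(g$genome, k = 10L)
  mp <- map_reads(pp$collapsed, idx)
  res <- identify_mirnas(mp$alignments, g$genome)
  list(spec = spec, genome = g$genome, truth = g$truth, reads = reads,
       collapsed = pp$collapsed, alignments = mp$alignments, res = res)
}
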