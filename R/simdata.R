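# Synthetic validation data: random genomes with planted pre-miRNA stem-loops
# and simulated small-RNA reads concentrated on the mature (and sparsely on
# the star) positions, plus mappable background noise.

#' Simulation specification
#'
#' @param genome_len genome length (nt).
#' @param n_hairpins number of planted stem-loop loci.
#' @param mature_len mature length (nt; plant matures are ~21 nt).
#' @param loop_len minimum spacer (terminal loop) length between mature and
#'   star; configurations whose spans imply a shorter spacer are rejected.
#' @param stem_mismatches substitutions introduced into the star relative to
#'   a perfect reverse complement of the mature.
#' @param span two-element range of the mature-to-star span (nt): distance
#'   from mature start to star end, the plant precursor length definition.
#'   One span per locus is drawn uniformly from the range.
#' @param reads_per_locus simulated reads per planted locus.
#' @param fraction_mature,fraction_star,fraction_noise read fractions per
#'   locus (must sum to 1): mature-positioned, star-positioned and uniform
#'   background.  Noise reads are genuine genome substrings (mappable) so
#'   they stress clustering and consistency, not the mapper.
#' @param position_jitter maximum start-position jitter (nt) of mature/star
#'   reads.
#' @param seed RNG seed; fixed seed gives byte-identical genomes and reads.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(genome_len = 100000L, n_hairpins = 20L, mature_len = 21L,
                     loop_len = 25L, stem_mismatches = 1L,
                     span = c(100L, 200L), reads_per_locus = 100L,
                     fraction_mature = 0.90, fraction_star = 0.05,
                     fraction_noise = 0.05, position_jitter = 1L,
                     seed = 1L) {
  if (length(span) == 1L) span <- c(span, span)
  stopifnot(abs(fraction_mature + fraction_star + fraction_noise - 1) < 1e-9,
            loop_len >= 0L, span[1L] <= span[2L],
            span[1L] >= 2L * mature_len + max(3L, loop_len))
  if (n_hairpins > 0L &&
      genome_len < n_hairpins * (2L * mature_len + span[2L] + 100L))
    stop("genome too small for ", n_hairpins, " non-overlapping loci; ",
         "enlarge genome_len to at least ",
         n_hairpins * (2L * mature_len + span[2L] + 100L), call. = FALSE)
  structure(list(genome_len = as.integer(genome_len),
                 n_hairpins = as.integer(n_hairpins),
                 mature_len = as.integer(mature_len),
                 loop_len = as.integer(loop_len),
                 stem_mismatches = as.integer(stem_mismatches),
                 span = as.integer(span),
                 reads_per_locus = as.integer(reads_per_locus),
                 fraction_mature = fraction_mature,
                 fraction_star = fraction_star,
                 fraction_noise = fraction_noise,
                 position_jitter = as.integer(position_jitter),
                 seed = as.integer(seed)), class = "sim_spec")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a base so it can no longer pair (WC or GU wobble) with `partner`
.break_pair <- function(partner) {
  ok <- switch(partner,
               A = c("A", "C", "G"),  # removes T (A-T); A cannot GU-pair
               C = c("A", "C", "T"),  # removes G
               G = c("A", "G"),       # removes C (WC) and T (GU)
               T = c("C", "T"))       # removes A (WC) and G (GU)
  sample(ok, 1L)
}

#' Generate a genome with planted stem-loop precursors
#'
#' The background is uniform random sequence; at each locus a mature, a
#' spacer and the (possibly mismatched) reverse complement of the mature are
#' planted so that the mature-to-star span equals the per-locus span drawn
#' from `spec$span`.  Loci are placed at random offsets inside equal
#' non-overlapping blocks of the genome.
#'
#' @param spec a [sim_spec()].
#' @return list with `genome` (named character vector, one chromosome
#'   `"sim1"`) and `truth`: data.frame of `chrom`, `strand`, `locus_start`,
#'   `locus_end`, `mature_start`, `mature_end`, `star_start`, `star_end`
#'   (1-based closed).
#' @export
make_genome <- function(spec = sim_spec()) {
  set.seed(spec$seed)
  genome <- .random_bases(spec$genome_len)
  truth <- data.frame(chrom = character(0), strand = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      mature_start = integer(0), mature_end = integer(0),
                      star_start = integer(0), star_end = integer(0),
                      stringsAsFactors = FALSE)
  if (spec$n_hairpins > 0L) {
    block <- spec$genome_len %/% spec$n_hairpins
    margin <- 40L
    for (h in seq_len(spec$n_hairpins)) {
      span <- if (spec$span[1L] == spec$span[2L]) spec$span[1L] else
        sample(spec$span[1L]:spec$span[2L], 1L)
      spacer <- span - 2L * spec$mature_len
      if (block < span + 2L * margin)
        stop("cannot place non-overlapping loci; enlarge genome_len",
             call. = FALSE)
      offset <- sample.int(block - span - 2L * margin, 1L) + margin
      m1 <- (h - 1L) * block + offset
      m2 <- m1 + spec$mature_len - 1L
      mature <- .random_bases(spec$mature_len)
      star <- revcomp(mature)
      if (spec$stem_mismatches > 0L) {
        pos <- sample.int(spec$mature_len, min(spec$stem_mismatches,
                                               spec$mature_len))
        for (p in pos) {
          partner <- substr(mature, spec$mature_len - p + 1L,
                            spec$mature_len - p + 1L)
          substr(star, p, p) <- .break_pair(partner)
        }
      }
      s1 <- m1 + spec$mature_len + spacer
      s2 <- s1 + spec$mature_len - 1L
      substr(genome, m1, m2) <- mature
      substr(genome, s1, s2) <- star
      truth[h, ] <- list("sim1", "+", m1, s2, m1, m2, s1, s2)
    }
  }
  list(genome = c(sim1 = genome), truth = truth)
}

.largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    o <- order(-(raw - counts))
    counts[o[seq_len(short)]] <- counts[o[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

#' Simulate small-RNA reads over planted loci
#'
#' Per locus, `reads_per_locus` reads are drawn (largest-remainder rounding
#' of the fractions): mature reads start at the mature start plus at most
#' `position_jitter` nt of jitter, star reads likewise at the star start,
#' and noise reads are uniform genome substrings of length 10-23 nt on a
#' random strand.  Qualities are constant Phred 40 so that quality filtering
#' is exercised by dedicated fixtures rather than by recovery tests.
#'
#' @param genome named character vector from [make_genome()].
#' @param truth truth table from [make_genome()].
#' @param spec a [sim_spec()].
#' @param path optional FASTQ output path.
#' @return read data.frame (as from [read_fastq()]); written to `path` as
#'   FASTQ when given.
#' @export
simulate_reads <- function(genome, truth, spec = sim_spec(), path = NULL) {
  set.seed(spec$seed + 1L)
  chrom <- genome[[1L]]
  counts <- .largest_remainder(spec$reads_per_locus,
                               c(spec$fraction_mature, spec$fraction_star,
                                 spec$fraction_noise))
  seqs <- character(0)
  jit <- function() if (spec$position_jitter == 0L) 0L else
    sample((-spec$position_jitter):spec$position_jitter, 1L)
  take <- function(start, len) {
    start <- max(1L, min(start, nchar(chrom) - len + 1L))
    substr(chrom, start, start + len - 1L)
  }
  n_iter <- if (nrow(truth) == 0L && spec$fraction_noise == 1) 1L else
    nrow(truth)
  for (h in seq_len(n_iter)) {
    if (h <= nrow(truth)) {
      for (r in seq_len(counts[1L]))
        seqs <- c(seqs, take(truth$mature_start[h] + jit(), spec$mature_len))
      for (r in seq_len(counts[2L]))
        seqs <- c(seqs, take(truth$star_start[h] + jit(), spec$mature_len))
    }
    for (r in seq_len(counts[3L])) {
      len <- sample(10:23, 1L)
      s <- take(sample.int(nchar(chrom) - len, 1L), len)
      if (sample(c(TRUE, FALSE), 1L)) s <- revcomp(s)
      seqs <- c(seqs, s)
    }
  }
  reads <- data.frame(id = sprintf("simread%05d", seq_along(seqs)),
                      seq = seqs,
                      qual = I(lapply(nchar(seqs), function(l)
                        rep(40L, l))),
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                      strrep("I", nchar(reads$seq))), path)
  }
  reads
}

#' Write a truth table as TSV (0-based half-open coordinates)
#'
#' @param truth truth table from [make_genome()] (1-based closed in memory).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth
  for (col in c("locus_start", "mature_start", "star_start"))
    out[[col]] <- out[[col]] - 1L
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
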