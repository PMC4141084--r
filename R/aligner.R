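# Mismatch-free mapping of collapsed reads to both strands of the genome.
# The exact string matching itself is Biostrings::matchPattern; this module
# owns the strand bookkeeping, the multimapper policy and copy-count
# pass-through.

#' Mapping parameters
#'
#' @param max_loci reads with more than this many total placements (both
#'   strands) are discarded as multimappers.
#' @return list of class `mapping_params`.
#' @export
mapping_params <- function(max_loci = 20L) {
  stopifnot(max_loci >= 1L)
  structure(list(max_loci = as.integer(max_loci)), class = "mapping_params")
}

#' Build a genome index for exact matching
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length; lookups of any genomic k-mer return its exact
#'   occurrence positions.  Use the minimum mappable read length.
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome, k = 10L) {
  if (k < 4L) stop("seed length k must be >= 4", call. = FALSE)
  structure(list(
    seqs = genome,
    dna = Biostrings::DNAStringSet(genome),
    k = as.integer(k)), class = "genome_index")
}

#' Look up exact occurrences of a k-mer (or any pattern) on the forward genome
#'
#' @param index a [build_index()] object.
#' @param pattern nucleotide string.
#' @return data.frame of `chrom`, `start` (1-based) for every exact forward
#'   occurrence.
#' @export
index_lookup <- function(index, pattern) {
  hits <- lapply(seq_along(index$dna), function(i) {
    m <- Biostrings::matchPattern(pattern, index$dna[[i]], fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(chrom = names(index$seqs)[i], start = BiocGenerics::start(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Map one collapsed read with zero mismatches
#'
#' Returns every placement on either strand where the read (or its reverse
#' complement, for "-") equals the genome exactly.  Reads with more than
#' `max_loci` total placements return no alignments (multimapper policy).
#'
#' @param read one-row collapsed read data.frame (`id`, `seq`, `count`).
#' @param index a [build_index()] object.
#' @param params a [mapping_params()] object.
#' @return alignment data.frame (possibly empty).
#' @export
map_exact <- function(read, index, params = mapping_params()) {
  if (grepl("N", read$seq, fixed = TRUE)) return(empty_alignments())
  fwd <- index_lookup(index, read$seq)
  rev <- index_lookup(index, revcomp(read$seq))
  n <- nrow(fwd) + nrow(rev)
  if (n == 0L || n > params$max_loci) return(empty_alignments())
  len <- nchar(read$seq)
  mk <- function(hits, strand) {
    if (nrow(hits) == 0L) return(NULL)
    data.frame(id = read$id, chrom = hits$chrom, start = hits$start,
               end = hits$start + len - 1L, strand = strand, seq = read$seq,
               count = read$count, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(fwd, "+"), mk(rev, "-"))
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Map a set of collapsed reads
#'
#' @param collapsed collapsed read data.frame.
#' @param index a [build_index()] object.
#' @param params a [mapping_params()] object.
#' @return list with `alignments` (sorted by chrom, strand, start) and
#'   `stats`: mapped read count, multimapper count, alignment count.
#' @export
map_reads <- function(collapsed, index, params = mapping_params()) {
  per_read <- lapply(seq_len(nrow(collapsed)), function(i)
    map_exact(collapsed[i, , drop = FALSE], index, params))
  hit <- vapply(per_read, nrow, integer(1)) > 0L
  aln <- do.call(rbind, c(list(empty_alignments()), per_read))
  aln <- aln[order(aln$chrom, aln$strand, aln$start, aln$end), , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       stats = c(mapped_reads = sum(hit), alignments = nrow(aln)))
}
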