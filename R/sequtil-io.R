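# Readers/writers for FASTA, FASTQ and SAM/BAM alignment records.
#
# In-memory representations are plain data frames:
#   reads:      id, seq, qual (list column of integer Phred vectors, or NULL)
#   collapsed:  id, seq, count
#   alignments: id, chrom, start, end, strand, seq, count   (1-based closed)
# `seq` on an alignment row is the read as sequenced; a "-" strand row means
# the read equals the reverse complement of the genome slice [start, end].

.normalize_bases <- function(seq, where) {
  s <- toupper(chartr("uU", "tT", seq))
  bad <- regexpr("[^ACGTN]", s)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of %s",
                 substr(s[i], bad[i], bad[i]), bad[i], where[i]), call. = FALSE)
  }
  s
}

#' Read a FASTA file of nucleotide sequences
#'
#' Multi-line sequences are concatenated; the identifier is the header up to
#' the first whitespace.  Lowercase and RNA (U) bases are normalized to
#' uppercase DNA; characters outside A,C,G,T,U,N are a fatal error.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of sequences (names are identifiers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- .normalize_bases(seqs, paste0("sequence '", ids, "'"))
  stats::setNames(seqs, ids)
}

#' Read a FASTQ file of short reads
#'
#' Expects 4-line records with Sanger Phred+33 qualities.  U is normalized to
#' T.  A record whose quality string length differs from its sequence length
#' is a fatal parse error naming the record.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `seq` and list column `qual`
#'   (integer Phred scores per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)", call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = I(list()), stringsAsFactors = FALSE))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hd <- which(substr(hd, 1L, 1L) != "@")
  if (length(bad_hd))
    stop("FASTQ record ", bad_hd[1L], ": header does not start with '@'",
         call. = FALSE)
  ids <- sub("\\s.*$", "", substring(hd, 2L))
  mism <- which(nchar(sq) != nchar(ql))
  if (length(mism))
    stop(sprintf(
      "FASTQ record '%s': sequence length %d != quality length %d",
      ids[mism[1L]], nchar(sq[mism[1L]]), nchar(ql[mism[1L]])), call. = FALSE)
  sq <- .normalize_bases(sq, paste0("read '", ids, "'"))
  qual <- lapply(ql, function(q) as.integer(charToRaw(q)) - 33L)
  neg <- which(vapply(qual, function(q) any(q < 0L), logical(1)))
  if (length(neg))
    stop("FASTQ record '", ids[neg[1L]], "': quality below Phred+33 range",
         call. = FALSE)
  data.frame(id = ids, seq = sq, qual = I(qual), stringsAsFactors = FALSE)
}

#' Read collapsed reads from FASTA
#'
#' Headers of the form `<id>_x<count>` carry the copy count; headers without
#' the suffix get count 1.
#'
#' @param path path to a FASTA file of unique read sequences.
#' @return data.frame with columns `id`, `seq`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  m <- regmatches(ids, regexec("^(.*)_x(\\d+)$", ids))
  count <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3L]) else 1L,
                  integer(1))
  id <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3L) m[[i]][2L] else ids[i], character(1))
  data.frame(id = id, seq = unname(seqs), count = count,
             stringsAsFactors = FALSE)
}

#' Write collapsed reads as FASTA
#'
#' @param collapsed data.frame with `id`, `seq`, `count`.
#' @param path output path; headers are `<id>_x<count>`.
#' @return invisibly, the path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  writeLines(paste0(">", collapsed$id, "_x", collapsed$count, "\n",
                    collapsed$seq),
             path)
  invisible(path)
}

empty_alignments <- function() {
  data.frame(id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), seq = character(0),
             count = integer(0), stringsAsFactors = FALSE)
}

#' Write alignments as SAM with XS copy-number tags
#'
#' Emits a valid SAM file with `@SQ` headers; POS is 1-based per the SAM
#' standard, reverse-strand records carry flag 16 and the reverse-complemented
#' (genome forward strand) SEQ, and every record carries `XS:i:<copy count>`.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param genome named character vector of reference sequences (for `@SQ`).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, genome, path) {
  unknown <- setdiff(unique(alignments$chrom), names(genome))
  if (length(unknown))
    stop("alignment references unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  if (nrow(alignments) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  rev <- alignments$strand == "-"
  seq_out <- alignments$seq
  seq_out[rev] <- revcomp(seq_out[rev])
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXS:i:%d",
                 alignments$id, ifelse(rev, 16L, 0L), alignments$chrom,
                 alignments$start, nchar(alignments$seq), seq_out,
                 alignments$count)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

.parse_sam_lines <- function(lines, path) {
  hdr <- lines[startsWith(lines, "@")]
  if (!any(startsWith(hdr, "@SQ")))
    stop("SAM file ", path, " has no @SQ header", call. = FALSE)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) return(empty_alignments())
  fields <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2L]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L  # drop unmapped
  fields <- fields[keep]
  flag <- flag[keep]
  if (length(fields) == 0L) return(empty_alignments())
  xs <- vapply(fields, function(f) {
    tag <- grep("^XS:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^XS:i:", "", tag[1L])) else 1L
  }, integer(1))
  seq_fwd <- vapply(fields, `[`, character(1), 10L)
  start <- vapply(fields, function(f) as.integer(f[4L]), integer(1))
  rev <- bitwAnd(flag, 16L) != 0L
  seq_read <- seq_fwd
  seq_read[rev] <- revcomp(seq_read[rev])
  data.frame(id = vapply(fields, `[`, character(1), 1L),
             chrom = vapply(fields, `[`, character(1), 3L),
             start = start,
             end = start + nchar(seq_fwd) - 1L,
             strand = ifelse(rev, "-", "+"),
             seq = seq_read,
             count = xs,
             stringsAsFactors = FALSE)
}

.read_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "seq"), tag = "XS")
  res <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- !is.na(res$pos)
  if (!any(keep)) return(empty_alignments())
  rev <- bitwAnd(res$flag[keep], 16L) != 0L
  seq_fwd <- as.character(res$seq)[keep]
  seq_read <- seq_fwd
  seq_read[rev] <- revcomp(seq_read[rev])
  xs <- res$tag$XS[keep]
  xs[is.na(xs)] <- 1L
  data.frame(id = res$qname[keep],
             chrom = as.character(res$rname)[keep],
             start = res$pos[keep],
             end = res$pos[keep] + nchar(seq_fwd) - 1L,
             strand = ifelse(rev, "-", "+"),
             seq = seq_read,
             count = as.integer(xs),
             stringsAsFactors = FALSE)
}

#' Read alignment records from SAM or BAM
#'
#' Unmapped records are skipped; records lacking the XS copy-number tag
#' default to count 1, so third-party alignments remain usable.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return alignment data.frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based closed), `strand`, `seq` (read orientation), `count`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(.read_bam(path))
  .parse_sam_lines(readLines(path), path)
}
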