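# Adapter trimming, length/quality filtering and exact-duplicate collapsing.

#' Preprocessing parameters
#'
#' @param adapter3 3' adapter sequence to trim (empty string disables
#'   trimming).
#' @param min_len,max_len kept read length range in nt (default 10-23, the
#'   usual plant small-RNA window).
#' @param min_mean_quality minimum mean Phred score for reads with qualities.
#' @param min_adapter_overlap minimum adapter prefix length that must match
#'   at the read 3' end before trimming.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter3 = "", min_len = 10L, max_len = 23L,
                              min_mean_quality = 20, min_adapter_overlap = 6L) {
  stopifnot(min_len > 0L, min_len <= max_len, min_mean_quality >= 0)
  if (nzchar(adapter3))
    adapter3 <- .normalize_bases(adapter3, "adapter")
  structure(list(adapter3 = adapter3, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_mean_quality = min_mean_quality,
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "preprocess_params")
}

#' Trim a 3' adapter from reads
#'
#' The leftmost exact occurrence of an adapter prefix (of length at least
#' `min_adapter_overlap`, or the full adapter followed by arbitrary bases)
#' reaching the read 3' end removes that suffix; qualities are trimmed in
#' step.  Reads without a match are kept whole.
#'
#' @param reads read data.frame from [read_fastq()].
#' @param params a [preprocess_params()] object.
#' @return the reads with adapters removed.
#' @export
trim_adapter <- function(reads, params = preprocess_params()) {
  ad <- params$adapter3
  if (!nzchar(ad) || nrow(reads) == 0L) return(reads)
  alen <- nchar(ad)
  min_ov <- params$min_adapter_overlap
  cut <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    for (p in seq_len(n)) {
      avail <- n - p + 1L
      l <- min(avail, alen)
      if (l < min_ov && l < alen) next
      # suffix must either be a prefix of the adapter, or start with the
      # full adapter (read-through into downstream sequence)
      if (substr(s, p, p + l - 1L) == substr(ad, 1L, l)) return(p - 1L)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, cut)
  if (!is.null(reads$qual))
    reads$qual <- I(mapply(function(q, k) q[seq_len(k)], reads$qual, cut,
                           SIMPLIFY = FALSE))
  reads
}

#' Filter reads on length and mean quality
#'
#' Drops reads outside the `[min_len, max_len]` nt range, reads containing N
#' (which cannot map mismatch-free), and reads whose mean Phred quality is
#' below `min_mean_quality` (when qualities are present).
#'
#' @param reads read data.frame.
#' @param params a [preprocess_params()] object.
#' @return list with `kept` (read data.frame) and `dropped`
#'   (data.frame of `id`, `reason` in `length`, `quality`, `ambiguous`).
#' @export
filter_reads <- function(reads, params = preprocess_params()) {
  len <- nchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  reason[len < params$min_len | len > params$max_len] <- "length"
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  reason[is.na(reason) & has_n] <- "ambiguous"
  if (!is.null(reads$qual)) {
    mq <- vapply(reads$qual, function(q)
      if (length(q)) mean(q) else 0, numeric(1))
    reason[is.na(reason) & mq < params$min_mean_quality] <- "quality"
  }
  keep <- is.na(reason)
  list(kept = reads[keep, , drop = FALSE],
       dropped = data.frame(id = reads$id[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Collapse exact duplicate reads
#'
#' Aggregates identical read sequences into one record with a copy count.
#' The representative identifier is the first seen; the sum of copy counts
#' equals the number of input reads.
#'
#' @param reads read data.frame (already filtered).
#' @return data.frame with columns `id`, `seq`, `count`, ordered by
#'   decreasing count then sequence.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  first <- !duplicated(reads$seq)
  counts <- table(factor(reads$seq, levels = reads$seq[first]))
  out <- data.frame(id = reads$id[first], seq = reads$seq[first],
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out[order(-out$count, out$seq), , drop = FALSE]
}

#' Run the full preprocessing stage
#'
#' @param reads read data.frame from [read_fastq()].
#' @param params a [preprocess_params()] object.
#' @return list with `collapsed` reads, `dropped` table and per-stage
#'   `stats` (named counts).
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  trimmed <- trim_adapter(reads, params)
  flt <- filter_reads(trimmed, params)
  collapsed <- collapse_reads(flt$kept)
  list(collapsed = collapsed, dropped = flt$dropped,
       stats = c(raw_reads = nrow(reads),
                 filtered_reads = nrow(flt$kept),
                 collapsed_reads = nrow(collapsed)))
}
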