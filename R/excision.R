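# Cluster mapped reads and excise candidate precursor windows anchored on
# the highest-expressed read of each cluster.
#
# Plant precursors put 100-200 nt between mature and star, so each cluster's
# anchor read spawns windows for each configured mature-to-star span (default
# 200 and 100 nt) under both arm hypotheses: mature on the 5' arm (star
# downstream in transcript orientation) and mature on the 3' arm (star
# upstream).

#' Excision parameters
#'
#' @param max_gap maximum gap (nt) between successive read intervals chained
#'   into one cluster.
#' @param flank extra nt kept beyond the mature on the non-star side.
#' @param spans mature-to-star span lengths (nt) to scan; the default scans
#'   200 nt and, as a rescue for short precursors, 100 nt.
#' @return list of class `excision_params`.
#' @export
excision_params <- function(max_gap = 30L, flank = 20L, spans = c(200L, 100L)) {
  stopifnot(max_gap >= 0L, flank >= 0L, length(spans) >= 1L, all(spans >= 25L))
  structure(list(max_gap = as.integer(max_gap), flank = as.integer(flank),
                 spans = as.integer(spans)), class = "excision_params")
}

#' Chain alignments into read clusters
#'
#' Alignments on the same chromosome and strand are chained into one cluster
#' when each successive interval starts within `max_gap` nt of the previous
#' interval's end.  The cluster anchor (putative mature) is the member with
#' the highest copy count; ties break to the leftmost start, then the
#' lexicographically smallest sequence.
#'
#' @param alignments alignment data.frame.
#' @param params an [excision_params()] object.
#' @return list of clusters, each a list with `chrom`, `strand`, `start`,
#'   `end`, `members` (alignment rows) and `anchor` (one member row).
#' @export
cluster_alignments <- function(alignments, params = excision_params()) {
  if (nrow(alignments) == 0L) return(list())
  key <- paste(alignments$chrom, alignments$strand, sep = "\r")
  out <- list()
  for (grp in split(alignments, key)) {
    ir <- IRanges::IRanges(start = grp$start, end = grp$end)
    red <- IRanges::reduce(ir, min.gapwidth = params$max_gap + 1L,
                           with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (j in seq_along(red)) {
      members <- grp[revmap[[j]], , drop = FALSE]
      rownames(members) <- NULL
      o <- order(-members$count, members$start, members$seq)
      out[[length(out) + 1L]] <- list(
        chrom = members$chrom[1L], strand = members$strand[1L],
        start = min(members$start), end = max(members$end),
        members = members, anchor = members[o[1L], , drop = FALSE])
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, `[[`, integer(1), "start"),
               vapply(out, `[[`, character(1), "strand"))
  out[ord]
}

#' Excise candidate precursor windows around a cluster anchor
#'
#' For each span L and each arm hypothesis one genomic window is emitted.
#' With the anchor read at `[s, e]` (1-based closed, genome coordinates) on
#' the "+" strand: the 5'-arm hypothesis (star downstream) yields
#' `[s - flank, e + L]`, the 3'-arm hypothesis `[s - L, e + flank]`.  On the
#' "-" strand the two are mirrored so that the hypothesis always refers to
#' transcript orientation.  Windows are clipped to chromosome bounds, the
#' candidate sequence is strand-adjusted (precursor 5'->3'), and duplicate
#' windows are emitted once.
#'
#' @param cluster a cluster from [cluster_alignments()].
#' @param genome named character vector of chromosome sequences.
#' @param params an [excision_params()] object.
#' @return list of candidates: `chrom`, `strand`, `start`, `end` (genome,
#'   1-based closed), `sequence` (precursor 5'->3'), `mature_start` (1-based
#'   within sequence), `mature_len`, `arm_hypothesis`, `span_len`, `anchor_id`.
#' @export
excise_candidates <- function(cluster, genome, params = excision_params()) {
  if (!cluster$chrom %in% names(genome))
    stop("cluster chromosome not in genome: ", cluster$chrom, call. = FALSE)
  chrom_len <- nchar(genome[[cluster$chrom]])
  s <- cluster$anchor$start
  e <- cluster$anchor$end
  mature_len <- e - s + 1L
  out <- list()
  seen <- character(0)
  for (L in params$spans) {
    for (hyp in c("five_prime", "three_prime")) {
      downstream_star <- (hyp == "five_prime") == (cluster$strand == "+")
      if (downstream_star) {
        w1 <- s - params$flank; w2 <- e + L
      } else {
        w1 <- s - L; w2 <- e + params$flank
      }
      w1 <- max(1L, w1); w2 <- min(chrom_len, w2)
      if (w2 - w1 + 1L < mature_len) next
      key <- paste(cluster$chrom, cluster$strand, w1, w2, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      seq <- substr(genome[[cluster$chrom]], w1, w2)
      if (cluster$strand == "+") {
        mstart <- s - w1 + 1L
      } else {
        seq <- revcomp(seq)
        mstart <- w2 - e + 1L
      }
      out[[length(out) + 1L]] <- list(
        chrom = cluster$chrom, strand = cluster$strand,
        start = w1, end = w2, sequence = seq,
        mature_start = mstart, mature_len = mature_len,
        arm_hypothesis = hyp, span_len = L,
        anchor_id = cluster$anchor$id)
    }
  }
  out
}
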