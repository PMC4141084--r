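# Parse folded candidates into hairpin geometry, infer the star sequence with
# the 2-nt 3' overhang convention, and apply the plant-adapted structural and
# read-consistency filters.

#' Hairpin filtering parameters
#'
#' @param min_loop minimum loop span (nt) between the mature-proximal and
#'   star-proximal ends of the duplex (default 25, the plant setting; the
#'   span includes the distance from the loop ends to mature/star).
#' @param max_incon_ratio maximum copy-weighted fraction of reads falling
#'   outside the mature and star regions; the comparison is strict (a ratio
#'   exactly at the threshold fails).  Loop reads count as inconsistent.
#' @param min_paired_fraction minimum fraction of mature bases that must be
#'   paired in the precursor structure.
#' @param consistency_shift_tol start/end drift (nt) still counted as lying
#'   on the mature or star (tolerance for imprecise DCL1 processing).
#' @param star_overhang length of the 3' overhang each duplex strand carries
#'   past the other (2 nt, the Dicer/DCL1 signature).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_loop = 25L, max_incon_ratio = 0.10,
                          min_paired_fraction = 0.60,
                          consistency_shift_tol = 3L, star_overhang = 2L) {
  stopifnot(min_loop >= 0L, max_incon_ratio > 0, max_incon_ratio < 1,
            min_paired_fraction >= 0, min_paired_fraction <= 1,
            consistency_shift_tol >= 0L, star_overhang >= 0L)
  structure(list(min_loop = as.integer(min_loop),
                 max_incon_ratio = max_incon_ratio,
                 min_paired_fraction = min_paired_fraction,
                 consistency_shift_tol = as.integer(consistency_shift_tol),
                 star_overhang = as.integer(star_overhang)),
            class = "filter_params")
}

.reject <- function(reason) structure(list(reason = reason),
                                      class = "hairpin_reject")

#' @export
print.hairpin_reject <- function(x, ...) {
  cat("rejected candidate:", x$reason, "\n")
  invisible(x)
}

#' Test whether a hairpin-stage result is a rejection
#'
#' @param x result of [parse_hairpin()], [infer_star()] or
#'   [read_consistency()].
#' @return TRUE when `x` carries a rejection reason.
#' @export
is_reject <- function(x) inherits(x, "hairpin_reject")

#' Parse a folded candidate into hairpin geometry
#'
#' The outermost base pair enclosing the whole mature interval defines the
#' stem; within it there must be exactly one terminal (hairpin) loop, whose
#' closing pair separates the 5' and 3' arms.  Internal loops and bulges are
#' permitted inside the arms.  Rejections: `multibranch` (more than one
#' terminal loop inside the enclosing stem), `mature_position` (no enclosing
#' pair, or the mature overlaps the terminal loop / spans both arms).
#'
#' @param candidate a candidate from [excise_candidates()].
#' @param fold a `fold_result` computed on `candidate$sequence`.
#' @return list with `arm5`, `arm3`, `terminal_loop`, `mature` (all
#'   `c(start, end)`, 1-based closed, precursor coordinates), `mature_arm`
#'   (`"five_prime"` or `"three_prime"`), `paired_fraction_mature`; or a
#'   `hairpin_reject`.
#' @export
parse_hairpin <- function(candidate, fold) {
  pt <- fold$pairs
  m1 <- candidate$mature_start
  m2 <- m1 + candidate$mature_len - 1L
  if (m2 > length(pt)) return(.reject("mature_position"))
  opening <- which(pt > seq_along(pt))
  enclosing <- opening[opening <= m1 & pt[opening] >= m2]
  if (length(enclosing) == 0L) return(.reject("mature_position"))
  a <- min(enclosing)
  b <- pt[a]
  # terminal loops inside [a, b]: opening pairs with nothing paired inside
  stem_open <- opening[opening >= a & pt[opening] <= b]
  is_terminal <- vapply(stem_open, function(p) {
    q <- pt[p]
    p + 1L > q - 1L || all(pt[(p + 1L):(q - 1L)] == 0L)
  }, logical(1))
  if (sum(is_terminal) > 1L) return(.reject("multibranch"))
  p <- stem_open[is_terminal]
  q <- pt[p]
  annotation <- list(
    arm5 = c(a, p), arm3 = c(q, b),
    terminal_loop = c(p + 1L, q - 1L),
    mature = c(m1, m2),
    paired_fraction_mature = mean(pt[m1:m2] > 0L))
  if (m1 >= a && m2 <= p) {
    annotation$mature_arm <- "five_prime"
  } else if (m1 >= q && m2 <= b) {
    annotation$mature_arm <- "three_prime"
  } else {
    return(.reject("mature_position"))
  }
  annotation
}

# partner position for a mature base, interpolating across unpaired bases
# (partners decrease as position increases within a stem, so extrapolation
# steps by -1 per nt)
.partner_of <- function(pt, paired, k) {
  if (pt[k] > 0L) return(pt[k])
  lo <- paired[paired < k]
  hi <- paired[paired > k]
  if (length(lo) && length(hi)) {
    l <- max(lo); r <- min(hi)
    return(as.integer(round(pt[l] + (k - l) * (pt[r] - pt[l]) / (r - l))))
  }
  if (length(lo)) return(pt[max(lo)] - (k - max(lo)))
  pt[min(hi)] + (min(hi) - k)
}

#' Infer the star interval from the mature's pairing partners
#'
#' The star occupies the positions pairing with the mature, shifted so each
#' duplex strand carries a `star_overhang`-nt 3' overhang (the classic 2-nt
#' DCL1 signature).  Unpaired mature bases are bridged by linear interpolation
#' between flanking paired partners; the star is clipped to the precursor.
#' Rejects with `unpaired_mature` when fewer than `min_paired_fraction` of
#' mature bases are paired, and `star_position` when the inferred interval is
#' degenerate.
#'
#' @param annotation output of [parse_hairpin()].
#' @param fold the `fold_result` for the precursor.
#' @param params a [filter_params()] object.
#' @return the annotation extended with `star = c(start, end)` and
#'   `loop_span`; or a `hairpin_reject`.
#' @export
infer_star <- function(annotation, fold, params = filter_params()) {
  if (is_reject(annotation)) return(annotation)
  pt <- fold$pairs
  m1 <- annotation$mature[1L]
  m2 <- annotation$mature[2L]
  if (annotation$paired_fraction_mature < params$min_paired_fraction)
    return(.reject("unpaired_mature"))
  paired <- (m1:m2)[pt[m1:m2] > 0L]
  ov <- params$star_overhang
  star_start <- .partner_of(pt, paired, m2) + ov
  star_end <- .partner_of(pt, paired, m1) + ov
  star_start <- max(1L, min(star_start, length(pt)))
  star_end <- max(1L, min(star_end, length(pt)))
  if (star_end <= star_start) return(.reject("star_position"))
  annotation$star <- c(star_start, star_end)
  annotation$loop_span <- if (star_start > m2) star_start - m2 - 1L
                          else m1 - star_end - 1L
  if (annotation$loop_span < 0L) return(.reject("star_position"))
  annotation
}

#' Check the minimum loop span
#'
#' The loop span is the number of precursor positions strictly between the
#' mature-proximal end of the duplex and the star-proximal end (star start
#' minus mature end for a 5'-arm mature, and mirrored otherwise).  Passes
#' when the span is at least `min_loop`.
#'
#' @param annotation output of [infer_star()].
#' @param params a [filter_params()] object.
#' @return TRUE (pass) or FALSE (fail).
#' @export
check_loop <- function(annotation, params = filter_params()) {
  annotation$loop_span >= params$min_loop
}

.to_precursor_coords <- function(members, candidate) {
  if (nrow(members) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      count = integer(0)))
  if (candidate$strand == "+") {
    data.frame(start = members$start - candidate$start + 1L,
               end = members$end - candidate$start + 1L,
               count = members$count)
  } else {
    data.frame(start = candidate$end - members$end + 1L,
               end = candidate$end - members$start + 1L,
               count = members$count)
  }
}

#' Copy-weighted read consistency over the mature/star duplex
#'
#' A read is consistent when its interval (precursor coordinates) lies
#' entirely within the mature or entirely within the star region, allowing a
#' positional drift of up to `consistency_shift_tol` nt while the read stays
#' inside the precursor.  Reads overlapping the loop or lying outside both
#' duplex regions are inconsistent -- loop reads are NOT forgiven, unlike in
#' the animal miRDeep convention, because plant loops are long enough to host
#' spurious reads.  The candidate passes when
#' `inconsistent / (consistent + inconsistent) < max_incon_ratio` (strict).
#'
#' @param members alignment rows on the candidate's chromosome and strand
#'   that overlap the candidate window (clusters are chained with a 30 nt
#'   gap, so the star reads of a long plant precursor are usually in a
#'   different cluster: pass every overlapping alignment, not one cluster).
#' @param candidate the precursor candidate.
#' @param annotation output of [infer_star()].
#' @param params a [filter_params()] object.
#' @return list with `ratio`, `consistent_copies`, `inconsistent_copies`,
#'   `mature_copies`, `star_copies`, `pass`; or a `hairpin_reject`
#'   (`no_reads`) when no copies overlap.
#' @export
read_consistency <- function(members, candidate, annotation,
                             params = filter_params()) {
  prec_len <- nchar(candidate$sequence)
  iv <- .to_precursor_coords(members, candidate)
  iv <- iv[iv$end >= 1L & iv$start <= prec_len, , drop = FALSE]
  total <- sum(iv$count)
  if (total == 0L) return(.reject("no_reads"))
  tol <- params$consistency_shift_tol
  inside <- function(region) {
    iv$start >= region[1L] - tol & iv$end <= region[2L] + tol &
      iv$start >= 1L & iv$end <= prec_len
  }
  on_mature <- inside(annotation$mature)
  on_star <- inside(annotation$star) & !on_mature
  consistent <- sum(iv$count[on_mature | on_star])
  inconsistent <- total - consistent
  ratio <- inconsistent / total
  # the star *bonus* demands biogenesis evidence: a star-positioned read has
  # both ends at the inferred star's ends (within the shift tolerance), not
  # merely any fragment inside the star region
  star_positioned <- on_star &
    abs(iv$start - annotation$star[1L]) <= tol &
    abs(iv$end - annotation$star[2L]) <= tol
  list(ratio = ratio,
       consistent_copies = consistent,
       inconsistent_copies = inconsistent,
       mature_copies = sum(iv$count[on_mature]),
       star_copies = sum(iv$count[star_positioned]),
       star_region_copies = sum(iv$count[on_star]),
       pass = ratio < params$max_incon_ratio)
}
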