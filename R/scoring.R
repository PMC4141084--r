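# Additive log-odds scoring of surviving candidates, deduplication of
# overlapping windows, known-miRNA annotation and precision/recall.
#
# The score is a deterministic sum of four evidence components (bits):
#   s_depth       log2(1 + consistent copies), capped
#   s_star        bonus when star reads are observed, penalty otherwise
#   s_energy      clamped linear term in folding energy per nt
#   s_consistency margin below the inconsistent-read threshold
# The component constants are fixed defaults of this package, exposed here.

#' Scoring parameters
#'
#' @param min_score minimum total score (bits) for a reported prediction.
#' @param depth_cap maximum value of the read-depth component (bits).
#' @param star_bonus component value when at least one star read is seen.
#' @param star_penalty component value when no star read is seen.
#' @param energy_scale reference folding energy density ((kcal/mol)/nt).
#' @param energy_slope bits per (kcal/mol)/nt above the reference; the
#'   energy component is clamped to `energy_clamp`.
#' @param energy_clamp two-element numeric, lower/upper clamp of `s_energy`.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(min_score = 4, depth_cap = 5, star_bonus = 3.9,
                           star_penalty = -1.3, energy_scale = 0.20,
                           energy_slope = 10, energy_clamp = c(-2, 3)) {
  stopifnot(is.finite(min_score), energy_clamp[1L] <= energy_clamp[2L])
  structure(list(min_score = min_score, depth_cap = depth_cap,
                 star_bonus = star_bonus, star_penalty = star_penalty,
                 energy_scale = energy_scale, energy_slope = energy_slope,
                 energy_clamp = energy_clamp), class = "scoring_params")
}

#' Score a candidate
#'
#' @param consistent_copies copy count of reads on the mature/star duplex.
#' @param star_copies copy count of reads on the star.
#' @param energy folding energy of the precursor (kcal/mol, <= 0).
#' @param precursor_len precursor length (nt).
#' @param incon_ratio copy-weighted inconsistent-read ratio.
#' @param params a [scoring_params()] object.
#' @param max_incon_ratio the filtering threshold the consistency margin is
#'   measured against.
#' @return list with `s_depth`, `s_star`, `s_energy`, `s_consistency`,
#'   `total` (all bits; total is their exact sum).
#' @export
score_candidate <- function(consistent_copies, star_copies, energy,
                            precursor_len, incon_ratio,
                            params = scoring_params(),
                            max_incon_ratio = 0.10) {
  s_depth <- min(log2(1 + consistent_copies), params$depth_cap)
  s_star <- if (star_copies >= 1L) params$star_bonus else params$star_penalty
  s_energy <- min(max(params$energy_slope *
                        (-energy / precursor_len - params$energy_scale),
                      params$energy_clamp[1L]), params$energy_clamp[2L])
  s_consistency <- log2(1 - incon_ratio) - log2(1 - max_incon_ratio)
  list(s_depth = s_depth, s_star = s_star, s_energy = s_energy,
       s_consistency = s_consistency,
       total = s_depth + s_star + s_energy + s_consistency)
}

#' Deduplicate overlapping predictions
#'
#' Among predictions whose precursor windows overlap by at least 1 nt on the
#' same chromosome and strand, only the highest-scoring one is kept; ties
#' break to the longer precursor, then the leftmost.
#'
#' @param predictions data.frame of predictions (needs `chrom`, `strand`,
#'   `start`, `end`, `score_total`).
#' @return list with `kept` and `superseded` subsets of `predictions`.
#' @export
deduplicate_predictions <- function(predictions) {
  n <- nrow(predictions)
  if (n <= 1L) return(list(kept = predictions,
                           superseded = predictions[0, , drop = FALSE]))
  len <- predictions$end - predictions$start + 1L
  o <- order(-predictions$score_total, -len, predictions$chrom,
             predictions$start)
  keep <- logical(n)
  for (i in o) {
    clash <- keep &
      predictions$chrom == predictions$chrom[i] &
      predictions$strand == predictions$strand[i] &
      predictions$start <= predictions$end[i] &
      predictions$end >= predictions$start[i]
    if (!any(clash)) keep[i] <- TRUE
  }
  list(kept = predictions[keep, , drop = FALSE],
       superseded = predictions[!keep, , drop = FALSE])
}

#' Match a predicted mature against known mature miRNAs
#'
#' A prediction matches a known mature when the sequences are identical, or
#' when they agree exactly over their overlap at a start shift of at most
#' 3 nt with a length difference of at most 2 nt (the usual isomiR
#' tolerance: 5'/3' end variants of the same duplex).  The first match in
#' input order is reported.
#'
#' @param mature_seq predicted mature sequence (DNA or RNA alphabet).
#' @param known named character vector of known mature sequences.
#' @return the matching identifier, or `NA_character_`.
#' @export
match_known <- function(mature_seq, known) {
  if (length(known) == 0L) return(NA_character_)
  m <- toupper(chartr("uU", "tT", mature_seq))
  ks <- toupper(chartr("uU", "tT", known))
  mv <- strsplit(m, "", fixed = TRUE)[[1L]]
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (m == k) return(names(known)[i])
    if (abs(nchar(m) - nchar(k)) > 2L) next
    kv <- strsplit(k, "", fixed = TRUE)[[1L]]
    for (d in -3L:3L) {
      # position j of the mature aligns with position j + d of the known
      j <- seq_along(mv)
      valid <- j + d >= 1L & j + d <= length(kv)
      if (!any(valid)) next
      if (all(mv[valid] == kv[j[valid] + d])) return(names(known)[i])
    }
  }
  NA_character_
}

#' Precision and recall against a known miRNA set
#'
#' Precision is the number of known miRNAs recovered (each counted once)
#' over the number of predictions; recall is the number of distinct known
#' miRNAs recovered over the total number of known miRNAs.
#'
#' @param matches character vector, one element per prediction: the matched
#'   known identifier or `NA`.
#' @param n_known total number of known miRNAs.
#' @return list with `precision` and `recall`.
#' @export
precision_recall <- function(matches, n_known) {
  if (n_known == 0L) stop("recall undefined for an empty known set",
                          call. = FALSE)
  n_matched <- length(unique(matches[!is.na(matches)]))
  if (length(matches) == 0L) {
    warning("no predictions; precision reported as 0")
    return(list(precision = 0, recall = 0))
  }
  list(precision = n_matched / length(matches),
       recall = n_matched / n_known)
}
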