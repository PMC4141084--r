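# RNA secondary structure prediction: single best structure and energy under
# a nearest-neighbor stacking model, restricted to multibranch-free (single
# terminal loop per stem) nested structures, plus an exhaustive enumeration
# oracle for verification on short sequences.
#
# Energies are handled internally as integer centi-kcal/mol so the dynamic
# program and the oracle agree exactly; user-facing energies are kcal/mol.

# pair codes: 1=AU 2=UA 3=GC 4=CG 5=GU 6=UG (T stands for U internally)
.PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.build_pair_code <- function() {
  m <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  m["A","T"] <- 1L; m["T","A"] <- 2L; m["G","C"] <- 3L
  m["C","G"] <- 4L; m["G","T"] <- 5L; m["T","G"] <- 6L
  m
}

# Turner-style RNA stack free energies (kcal/mol) at 37 C for the 36 ordered
# WC/GU doublets; entry [p1, p2] is pair p2 stacked immediately inside p1.
# The two destabilizing GU-on-GU entries are floored at -0.30 so that every
# stack is stabilizing (the model rejects those helices downstream anyway).
.build_stack <- function() {
  v <- c(
    # inner:   AU     UA     GC     CG     GU     UG      outer
            -0.93, -1.10, -2.08, -2.24, -0.55, -1.36,   # AU
            -1.33, -0.93, -2.11, -2.35, -1.00, -1.27,   # UA
            -2.35, -2.24, -3.26, -3.42, -1.53, -2.51,   # GC
            -2.11, -2.08, -2.36, -3.26, -1.41, -2.11,   # CG
            -1.27, -1.36, -2.11, -2.51, -0.50, -0.30,   # GU
            -1.00, -0.55, -1.41, -1.53, -0.30, -0.50)   # UG
  matrix(as.integer(round(v * 100)), 6, 6, byrow = TRUE,
         dimnames = list(.PAIR_NAMES, .PAIR_NAMES))
}

.loop_vec <- function(tab, first_size, base_size, max_size) {
  # tab: penalties (kcal) for sizes first_size..(first_size+length(tab)-1);
  # beyond the table: Jacobson-Stockmayer log extrapolation from base_size
  sizes <- seq_len(max_size)
  out <- rep(NA_real_, max_size)
  idx <- seq_along(tab) + first_size - 1L
  out[idx] <- tab
  if (first_size > 1L) out[seq_len(first_size - 1L)] <- 99
  last <- tab[length(tab)]
  big <- sizes > max(idx)
  out[big] <- last + 1.08 * log(sizes[big] / max(idx))
  as.integer(round(out * 100))
}

#' Nearest-neighbor energy model for hairpin folding
#'
#' Stacking energies for the 36 WC/G-U doublets plus size-dependent hairpin,
#' bulge and internal loop penalties (log-extrapolated beyond the tabulated
#' sizes), at fixed 37 degrees C.  Multibranch loops are not modeled: the
#' downstream hairpin filters reject multi-loop structures, so the fold is
#' restricted to single-terminal-loop stems (any number side by side at the
#' exterior level).
#'
#' @param min_hairpin_unpaired minimum unpaired positions closed by a pair.
#' @param max_interior maximum total unpaired size of an interior loop/bulge.
#' @param max_len longest sequence the penalty tables are precomputed for.
#' @return list of class `energy_model`.
#' @export
energy_model <- function(min_hairpin_unpaired = 3L, max_interior = 30L,
                         max_len = 1500L) {
  structure(list(
    pair_code = .build_pair_code(),
    stack = .build_stack(),
    hairpin_pen = .loop_vec(c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4), 3L, 9L,
                            max_len),
    bulge_pen = .loop_vec(c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4), 1L, 6L, max_len),
    internal_pen = .loop_vec(c(1.5, 1.8, 2.0, 2.2, 2.5), 2L, 6L, max_len),
    min_hairpin = as.integer(min_hairpin_unpaired),
    max_interior = as.integer(max_interior)), class = "energy_model")
}

.pairs_to_dotbracket <- function(pairs) {
  db <- rep(".", length(pairs))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs > 0L & pairs < seq_along(pairs)] <- ")"
  paste(db, collapse = "")
}

.fold_result <- function(sequence, pairs, energy_centi) {
  structure(list(sequence = sequence, pairs = pairs,
                 dotbracket = .pairs_to_dotbracket(pairs),
                 energy = energy_centi / 100), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (", format(x$energy, nsmall = 2),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Fold a sequence into its minimum-energy hairpin structure
#'
#' Dynamic programming over subintervals under the [energy_model()];
#' pseudoknots and multibranch loops are excluded, pairs are Watson-Crick or
#' G-U wobble, hairpin loops have at least `min_hairpin_unpaired` positions.
#' The empty structure has energy 0, so the optimum is never positive.
#' Traceback ties prefer the pair (i,j) with smallest i, then largest j.
#'
#' @param sequence nucleotide string over A,C,G,T/U,N; N positions are forced
#'   unpaired.
#' @param model an [energy_model()].
#' @return `fold_result` with `dotbracket`, `pairs` (partner index per
#'   position, 0 = unpaired) and `energy` (kcal/mol).
#' @export
fold <- function(sequence, model = energy_model()) {
  sequence <- toupper(chartr("uU", "tT", sequence))
  codes <- base_codes(sequence)
  if (length(codes) > length(model$hairpin_pen))
    stop("sequence longer than the model's precomputed penalty tables",
         call. = FALSE)
  res <- .fold_dp(codes, as.integer(model$pair_code),
                  as.integer(model$stack), model$hairpin_pen,
                  model$bulge_pen, model$internal_pen,
                  model$min_hairpin, model$max_interior)
  .fold_result(sequence, res$pairs, res$energy)
}

# --- exhaustive oracle -------------------------------------------------------

# independent scoring of an explicit pair list (two-column matrix, rows (i,j))
.score_pairs <- function(pm, codes, model) {
  if (nrow(pm) == 0L) return(0L)
  pc <- function(i, j) {
    a <- codes[i]; b <- codes[j]
    if (is.na(a) || is.na(b)) 0L else model$pair_code[a, b]
  }
  e <- 0L
  for (r in seq_len(nrow(pm))) {
    a <- pm[r, 1L]; b <- pm[r, 2L]
    inside <- pm[, 1L] > a & pm[, 2L] < b
    if (!any(inside)) {
      e <- e + model$hairpin_pen[b - a - 1L]
    } else {
      k <- which(inside)[which.min(pm[inside, 1L])]
      p <- pm[k, 1L]; q <- pm[k, 2L]
      l1 <- p - a - 1L; l2 <- b - q - 1L
      e <- e + if (l1 == 0L && l2 == 0L) model$stack[pc(a, b), pc(p, q)]
               else if (l1 == 0L || l2 == 0L) model$bulge_pen[l1 + l2]
               else model$internal_pen[l1 + l2]
    }
  }
  e
}

# deterministic tie-break among equal-energy structures: compare pair lists
# sorted by i, element-wise (smaller i wins, then larger j); a structure that
# extends another by more pairs wins.  Returns TRUE if a beats b.
.struct_before <- function(a, b) {
  a <- a[order(a[, 1L]), , drop = FALSE]
  b <- b[order(b[, 1L]), , drop = FALSE]
  k <- min(nrow(a), nrow(b))
  if (k > 0L) for (r in seq_len(k)) {
    if (a[r, 1L] != b[r, 1L]) return(a[r, 1L] < b[r, 1L])
    if (a[r, 2L] != b[r, 2L]) return(a[r, 2L] > b[r, 2L])
  }
  nrow(a) > nrow(b)
}

#' Exhaustive folding oracle
#'
#' Enumerates every valid nested, multibranch-free structure of a short
#' sequence, scores each with an independent walk over its loops, and returns
#' the minimum-energy structure under the same tie-break as [fold()].  Only
#' intended for verification; refuses sequences longer than 25 nt.
#'
#' @inheritParams fold
#' @return a `fold_result`.
#' @export
fold_oracle <- function(sequence, model = energy_model()) {
  sequence <- toupper(chartr("uU", "tT", sequence))
  if (nchar(sequence) > 25L)
    stop("fold_oracle enumerates exhaustively; sequence must be <= 25 nt",
         call. = FALSE)
  codes <- base_codes(sequence)
  n <- length(codes)
  minh <- model$min_hairpin
  pairable <- function(i, j) {
    if (j - i - 1L < minh) return(FALSE)
    a <- codes[i]; b <- codes[j]
    !is.na(a) && !is.na(b) && model$pair_code[a, b] > 0L
  }
  memo_c <- new.env(parent = emptyenv())
  memo_e <- new.env(parent = emptyenv())
  enum_closed <- function(i, j) {
    key <- paste0(i, ":", j)
    if (!is.null(memo_c[[key]])) return(memo_c[[key]])
    out <- list()
    if (pairable(i, j)) {
      out[[1L]] <- matrix(c(i, j), 1L)
      for (p in (i + 1L):(j - 1L)) {
        if (p - i - 1L > model$max_interior) break
        if (p + minh + 1L > j - 1L) break
        for (q in (j - 1L):(p + minh + 1L)) {
          if ((p - i - 1L) + (j - q - 1L) > model$max_interior) break
          for (S in enum_closed(p, q))
            out[[length(out) + 1L]] <- rbind(c(i, j), S)
        }
      }
    }
    memo_c[[key]] <- out
    out
  }
  enum_ext <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), 0L, 2L)))
    key <- paste0(i, ":", j)
    if (!is.null(memo_e[[key]])) return(memo_e[[key]])
    out <- enum_ext(i + 1L, j)
    if (i + minh + 1L <= j) for (k in (i + minh + 1L):j) {
      closed <- enum_closed(i, k)
      if (length(closed)) for (S in closed) for (Tl in enum_ext(k + 1L, j))
        out[[length(out) + 1L]] <- rbind(S, Tl)
    }
    memo_e[[key]] <- out
    out
  }
  structs <- if (n == 0L) list(matrix(integer(0), 0L, 2L)) else enum_ext(1L, n)
  energies <- vapply(structs, .score_pairs, integer(1), codes = codes,
                     model = model)
  best_e <- min(energies)
  cand <- structs[energies == best_e]
  best <- cand[[1L]]
  if (length(cand) > 1L) for (s in cand[-1L])
    if (.struct_before(s, best)) best <- s
  pairs <- integer(n)
  if (nrow(best)) {
    pairs[best[, 1L]] <- best[, 2L]
    pairs[best[, 2L]] <- best[, 1L]
  }
  .fold_result(sequence, pairs, best_e)
}
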