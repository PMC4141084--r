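# Result files and hairpin-with-reads rendering (text and SVG).
#
# Six files are written per run:
#   known_mir_expression.tsv  predictions matching known matures
#   novel_predictions.tsv     remaining predictions
#   rejected_candidates.tsv   candidate windows with rejection reasons
#   mapping_stats.tsv         per-stage record counts
#   hairpins.txt              text hairpin-with-reads diagrams
#   run_summary.txt           parameter snapshot and file manifest
# TSVs have one header line, tab separators, LF endings, and deterministic
# row order (score descending, then coordinates).

.pred_columns <- c("id", "chrom", "start", "end", "strand", "score_total",
                   "score_depth", "score_star", "score_energy",
                   "score_consistency", "mature_seq", "star_seq",
                   "precursor_seq", "mature_copies", "star_copies",
                   "total_copies", "incon_ratio", "energy", "dotbracket",
                   "known_match")

.order_predictions <- function(predictions) {
  if (nrow(predictions) == 0L) return(predictions)
  predictions[order(-predictions$score_total, predictions$chrom,
                    predictions$start, predictions$strand), , drop = FALSE]
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 4,
                                                 format = "f"))
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write the six result files
#'
#' @param predictions prediction data.frame (deduplicated, scored, annotated;
#'   see [identify_mirnas()]).
#' @param rejected data.frame of rejected candidates (`chrom`, `start`,
#'   `end`, `strand`, `span_len`, `arm_hypothesis`, `reason`).
#' @param stats named integer vector of per-stage counts.
#' @param params_snapshot named list of run parameters for the summary.
#' @param outdir output directory (created if needed).
#' @param hairpin_blocks optional character vector of pre-rendered text
#'   diagrams, one per prediction (in prediction order).
#' @return invisibly, the file manifest (named paths).
#' @export
write_results <- function(predictions, rejected, stats, params_snapshot,
                          outdir, hairpin_blocks = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  predictions <- .order_predictions(predictions)
  empty <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(.pred_columns)), .pred_columns))
  known <- if (nrow(predictions)) predictions[!is.na(predictions$known_match),
                                              .pred_columns] else empty
  novel <- if (nrow(predictions)) predictions[is.na(predictions$known_match),
                                              .pred_columns] else empty
  rej_cols <- c("chrom", "start", "end", "strand", "span_len",
                "arm_hypothesis", "reason")
  if (nrow(rejected) == 0L)
    rejected <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(rej_cols)), rej_cols))
  rejected <- rejected[order(rejected$chrom, rejected$start, rejected$end,
                             rejected$strand, rejected$reason), rej_cols,
                       drop = FALSE]
  manifest <- c(
    known_mir_expression = file.path(outdir, "known_mir_expression.tsv"),
    novel_predictions = file.path(outdir, "novel_predictions.tsv"),
    rejected_candidates = file.path(outdir, "rejected_candidates.tsv"),
    mapping_stats = file.path(outdir, "mapping_stats.tsv"),
    hairpins = file.path(outdir, "hairpins.txt"),
    run_summary = file.path(outdir, "run_summary.txt"))
  .write_tsv(known, manifest[["known_mir_expression"]])
  .write_tsv(novel, manifest[["novel_predictions"]])
  .write_tsv(rejected, manifest[["rejected_candidates"]])
  .write_tsv(data.frame(stage = names(stats), count = as.integer(stats)),
             manifest[["mapping_stats"]])
  writeLines(hairpin_blocks %||% character(0), manifest[["hairpins"]])
  snap <- vapply(params_snapshot, function(v)
    paste(format(v, trim = TRUE), collapse = ","), character(1))
  writeLines(c("# run summary",
               paste0(names(snap), " = ", snap),
               "# files",
               paste0(names(manifest), "\t", basename(manifest))),
             manifest[["run_summary"]])
  invisible(manifest)
}

# character grid shared by the text and SVG renderers
.hairpin_grid <- function(prediction, members) {
  prec <- prediction$precursor_seq
  n <- nchar(prec)
  m1 <- prediction$mature_start
  m2 <- m1 + prediction$mature_len - 1L
  seq_line <- tolower(to_rna(prec))
  substr(seq_line, m1, m2) <- toupper(substr(seq_line, m1, m2))
  lines <- c(seq_line, prediction$dotbracket)
  if (nrow(members)) {
    cand <- list(strand = prediction$strand, start = prediction$start,
                 end = prediction$end, sequence = prec)
    iv <- .to_precursor_coords(members, cand)
    iv$seq <- members$seq
    iv <- iv[order(-iv$count, iv$start), , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      s <- iv$start[r]; e <- iv$end[r]
      rd <- to_rna(iv$seq[r])
      if (s < 1L) { rd <- substr(rd, 2L - s, nchar(rd)); s <- 1L }
      if (e > n) rd <- substr(rd, 1L, nchar(rd) - (e - n))
      lines <- c(lines, paste0(strrep(".", s - 1L), rd,
                               strrep(".", n - s + 1L - nchar(rd)),
                               " x", iv$count[r]))
    }
  }
  lines
}

#' Render a hairpin-with-reads diagram as text
#'
#' Emits the precursor (RNA alphabet; mature uppercase, context lowercase),
#' the dot-bracket structure beneath it, then one line per distinct read,
#' aligned at its precursor offset, padded with dots and suffixed with
#' `x<copy count>`, sorted by copy count descending.  Reads sticking out of
#' the window are clipped.
#'
#' @param prediction one prediction (a one-row data.frame or list with
#'   `precursor_seq`, `dotbracket`, `mature_start`, `mature_len`, `strand`,
#'   `start`, `end`, `id`).
#' @param members alignment rows overlapping the precursor window.
#' @return character vector of lines.
#' @export
render_hairpin_text <- function(prediction, members) {
  c(sprintf(">%s %s:%d-%d(%s) score=%.2f", prediction$id, prediction$chrom,
            prediction$start, prediction$end, prediction$strand,
            prediction$score_total),
    .hairpin_grid(prediction, members))
}

#' Render a hairpin-with-reads diagram as SVG
#'
#' Monospace glyph layout mirroring [render_hairpin_text()] (identical
#' character grid); the mature positions of the sequence line are styled
#' with a red fill.  One `<text>` element per rendered line.
#'
#' @inheritParams render_hairpin_text
#' @param path output path for a standalone SVG 1.1 file.
#' @return invisibly, the path.
#' @export
render_hairpin_svg <- function(prediction, members, path) {
  grid <- .hairpin_grid(prediction, members)
  char_w <- 8; line_h <- 16
  width <- (max(nchar(grid)) + 2) * char_w
  height <- (length(grid) + 2) * line_h
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = as.character(width), height = as.character(height))
  m1 <- prediction$mature_start
  m2 <- m1 + prediction$mature_len - 1L
  for (i in seq_along(grid)) {
    node <- xml2::xml_add_child(
      doc, "text", x = as.character(char_w),
      y = as.character(i * line_h),
      "font-family" = "monospace", "font-size" = "13",
      "xml:space" = "preserve")
    if (i == 1L) {
      # sequence line: mature glyphs red, context black
      xml2::xml_add_child(node, "tspan", substr(grid[i], 1L, m1 - 1L),
                          fill = "black")
      xml2::xml_add_child(node, "tspan", substr(grid[i], m1, m2),
                          fill = "red")
      xml2::xml_add_child(node, "tspan",
                          substr(grid[i], m2 + 1L, nchar(grid[i])),
                          fill = "black")
    } else {
      xml2::xml_set_text(node, grid[i])
    }
  }
  # no pretty-printing: indentation would leak whitespace into the glyph grid
  xml2::write_xml(doc, path, options = "no_declaration")
  invisible(path)
}
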