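# End-to-end orchestration: identification from mapped reads, full runs from
# FASTQ/FASTA, and extension-based dispatch.

#' Run configuration
#'
#' @param input_path reads (`.fastq`), collapsed reads (`.fa`/`.fasta`,
#'   headers `<id>_x<count>`) or mapped reads (`.sam`/`.bam` with XS
#'   copy-number tags).
#' @param genome_path reference genome FASTA.
#' @param known_path optional FASTA of known mature miRNAs (miRBase-style
#'   headers tolerated).
#' @param outdir output directory.
#' @param preprocess,mapping,excision,filters,scoring,model parameter
#'   objects; defaults as in the owning constructors.
#' @param write_bed also write candidate windows as BED (0-based half-open).
#' @param seed RNG seed recorded in the summary (the pipeline itself is
#'   deterministic; the seed matters for simulation subcommands).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_path, genome_path, known_path = NULL,
                       outdir = "plantmir_out",
                       preprocess = preprocess_params(),
                       mapping = mapping_params(),
                       excision = excision_params(),
                       filters = filter_params(),
                       scoring = scoring_params(),
                       model = energy_model(),
                       write_bed = FALSE, seed = 1L) {
  structure(list(input_path = input_path, genome_path = genome_path,
                 known_path = known_path, outdir = outdir,
                 preprocess = preprocess, mapping = mapping,
                 excision = excision, filters = filters, scoring = scoring,
                 model = model, write_bed = write_bed,
                 seed = as.integer(seed)), class = "run_config")
}

.members_in_window <- function(alignments, chrom, strand, start, end) {
  alignments[alignments$chrom == chrom & alignments$strand == strand &
               alignments$start <= end & alignments$end >= start, ,
             drop = FALSE]
}

#' Identify miRNAs from mapped reads
#'
#' Clusters alignments, excises mature-anchored precursor windows, folds
#' each window, applies the hairpin/star/loop/consistency filters, scores
#' survivors, deduplicates overlapping windows and annotates against known
#' matures.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param genome named character vector of chromosome sequences.
#' @param known optional named character vector of known mature sequences.
#' @param excision,filters,scoring,model parameter objects.
#' @return list with `predictions` (data.frame), `rejected` (data.frame with
#'   rejection reasons) and `stats` (named counts).
#' @export
identify_mirnas <- function(alignments, genome, known = NULL,
                            excision = excision_params(),
                            filters = filter_params(),
                            scoring = scoring_params(),
                            model = energy_model()) {
  clusters <- cluster_alignments(alignments, excision)
  candidates <- list()
  seen <- character(0)
  for (cl in clusters) {
    for (cand in excise_candidates(cl, genome, excision)) {
      key <- paste(cand$chrom, cand$strand, cand$start, cand$end,
                   cand$mature_start, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      candidates[[length(candidates) + 1L]] <- cand
    }
  }

  preds <- list()
  rejected <- list()
  n_folded <- 0L
  reject_row <- function(cand, reason) {
    data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
               strand = cand$strand, span_len = cand$span_len,
               arm_hypothesis = cand$arm_hypothesis, reason = reason,
               stringsAsFactors = FALSE)
  }
  for (cand in candidates) {
    fr <- fold(cand$sequence, model)
    n_folded <- n_folded + 1L
    ann <- parse_hairpin(cand, fr)
    if (!is_reject(ann)) ann <- infer_star(ann, fr, filters)
    if (is_reject(ann)) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand, ann$reason)
      next
    }
    if (!check_loop(ann, filters)) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand, "short_loop")
      next
    }
    members <- .members_in_window(alignments, cand$chrom, cand$strand,
                                  cand$start, cand$end)
    cons <- read_consistency(members, cand, ann, filters)
    if (is_reject(cons)) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand, cons$reason)
      next
    }
    if (!cons$pass) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand,
                                                      "inconsistent_reads")
      next
    }
    # the mature is by definition the higher-expressed duplex arm; a window
    # whose star region out-expresses its mature is the mirrored (star-
    # anchored) hypothesis of the same locus and is dropped here
    if (cons$star_region_copies > cons$mature_copies) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand, "star_dominant")
      next
    }
    sc <- score_candidate(cons$consistent_copies, cons$star_copies,
                          fr$energy, nchar(cand$sequence), cons$ratio,
                          scoring, filters$max_incon_ratio)
    if (sc$total < scoring$min_score) {
      rejected[[length(rejected) + 1L]] <- reject_row(cand, "low_score")
      next
    }
    m1 <- cand$mature_start
    m2 <- m1 + cand$mature_len - 1L
    preds[[length(preds) + 1L]] <- data.frame(
      chrom = cand$chrom, start = cand$start, end = cand$end,
      strand = cand$strand, span_len = cand$span_len,
      arm_hypothesis = cand$arm_hypothesis,
      mature_start = m1, mature_len = cand$mature_len,
      score_total = sc$total, score_depth = sc$s_depth,
      score_star = sc$s_star, score_energy = sc$s_energy,
      score_consistency = sc$s_consistency,
      mature_seq = to_rna(substr(cand$sequence, m1, m2)),
      star_seq = to_rna(substr(cand$sequence, ann$star[1L], ann$star[2L])),
      precursor_seq = cand$sequence,
      mature_copies = cons$mature_copies, star_copies = cons$star_copies,
      total_copies = cons$consistent_copies + cons$inconsistent_copies,
      incon_ratio = cons$ratio, energy = fr$energy,
      dotbracket = fr$dotbracket, loop_span = ann$loop_span,
      stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  if (is.null(predictions))
    predictions <- data.frame()
  rejected <- do.call(rbind, rejected)
  if (is.null(rejected))
    rejected <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           span_len = integer(0),
                           arm_hypothesis = character(0),
                           reason = character(0), stringsAsFactors = FALSE)

  if (nrow(predictions)) {
    dd <- deduplicate_predictions(predictions)
    predictions <- dd$kept
    if (nrow(dd$superseded))
      rejected <- rbind(rejected,
                        dd$superseded[, names(rejected)[1:6], drop = FALSE] |>
                          transform(reason = "superseded"))
    predictions$known_match <- vapply(predictions$mature_seq, match_known,
                                      character(1), known = known %||%
                                        character(0), USE.NAMES = FALSE)
    predictions <- .order_predictions(predictions)
    predictions$id <- sprintf("pred%03d", seq_len(nrow(predictions)))
    rownames(predictions) <- NULL
  } else {
    predictions <- data.frame(
      id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), span_len = integer(0),
      arm_hypothesis = character(0), mature_start = integer(0),
      mature_len = integer(0), score_total = numeric(0),
      score_depth = numeric(0), score_star = numeric(0),
      score_energy = numeric(0), score_consistency = numeric(0),
      mature_seq = character(0), star_seq = character(0),
      precursor_seq = character(0), mature_copies = integer(0),
      star_copies = integer(0), total_copies = integer(0),
      incon_ratio = numeric(0), energy = numeric(0),
      dotbracket = character(0), loop_span = integer(0),
      known_match = character(0), stringsAsFactors = FALSE)
  }
  list(predictions = predictions, rejected = rejected,
       stats = c(clusters = length(clusters),
                 candidates = length(candidates),
                 folded = n_folded,
                 passed_filters = nrow(predictions) +
                   sum(rejected$reason %in% c("low_score", "superseded")),
                 predictions = nrow(predictions)))
}

.read_known <- function(path) {
  if (is.null(path)) return(NULL)
  read_fasta(path)
}

#' Dispatch a run on input file extension
#'
#' `.fastq`/`.fq` inputs get the full pipeline (preprocess, collapse, map,
#' identify); `.fa`/`.fasta` are treated as already-collapsed reads
#' (`_x<count>` headers; absent counts default to 1) and are mapped and
#' identified; `.sam`/`.bam` skip straight to identification.  Anything
#' else is a usage error (a condition of class `usage_error`).
#'
#' @param config a [run_config()].
#' @return invisibly, the result of [run_pipeline()].
#' @export
dispatch <- function(config) {
  ext <- tolower(sub(".*\\.", "", config$input_path))
  mode <- switch(ext,
                 fastq = , fq = "fastq",
                 fa = , fasta = "collapsed",
                 sam = , bam = "alignments",
                 stop(structure(class = c("usage_error", "error",
                                          "condition"),
                                list(message = paste0(
                                  "unrecognized input extension '.", ext,
                                  "'; accepted: .fastq, .fq, .fa, .fasta, ",
                                  ".sam, .bam"), call = NULL))))
  if (is.null(config$genome_path))
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = "a reference genome is required",
                        call = NULL)))
  run_pipeline(config, mode)
}

#' Run the pipeline
#'
#' @param config a [run_config()].
#' @param mode `"fastq"`, `"collapsed"` or `"alignments"` (normally set by
#'   [dispatch()] from the input extension).
#' @return list with `predictions`, `rejected`, `stats`, `manifest`
#'   (paths of the six output files).
#' @export
run_pipeline <- function(config, mode = "fastq") {
  genome <- read_fasta(config$genome_path)
  known <- .read_known(config$known_path)
  stats <- integer(0)
  if (mode == "fastq") {
    reads <- read_fastq(config$input_path)
    pp <- preprocess_reads(reads, config$preprocess)
    collapsed <- pp$collapsed
    stats <- pp$stats
  } else if (mode == "collapsed") {
    collapsed <- read_collapsed_fasta(config$input_path)
    stats <- c(raw_reads = sum(collapsed$count),
               filtered_reads = sum(collapsed$count),
               collapsed_reads = nrow(collapsed))
  }
  if (mode %in% c("fastq", "collapsed")) {
    index <- build_index(genome, k = config$preprocess$min_len)
    mp <- map_reads(collapsed, index, config$mapping)
    alignments <- mp$alignments
    stats <- c(stats, mp$stats)
  } else {
    alignments <- read_alignments(config$input_path)
    stats <- c(alignments = nrow(alignments))
  }
  res <- identify_mirnas(alignments, genome, known,
                         config$excision, config$filters, config$scoring,
                         config$model)
  stats <- c(stats, res$stats)

  blocks <- character(0)
  if (nrow(res$predictions)) {
    blocks <- unlist(lapply(seq_len(nrow(res$predictions)), function(i) {
      p <- res$predictions[i, , drop = FALSE]
      members <- .members_in_window(alignments, p$chrom, p$strand,
                                    p$start, p$end)
      c(render_hairpin_text(p, members), "")
    }))
  }
  snapshot <- list(
    input = config$input_path, genome = config$genome_path,
    known = config$known_path %||% "none", mode = mode,
    seed = config$seed,
    min_read_len = config$preprocess$min_len,
    max_read_len = config$preprocess$max_len,
    adapter = if (nzchar(config$preprocess$adapter3))
      config$preprocess$adapter3 else "none",
    max_loci = config$mapping$max_loci,
    spans = config$excision$spans, flank = config$excision$flank,
    max_gap = config$excision$max_gap,
    min_loop = config$filters$min_loop,
    max_incon_ratio = config$filters$max_incon_ratio,
    min_score = config$scoring$min_score)
  manifest <- write_results(res$predictions, res$rejected, stats, snapshot,
                            config$outdir, blocks)
  if (isTRUE(config$write_bed) && nrow(res$predictions)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", res$predictions$chrom,
                   res$predictions$start - 1L, res$predictions$end,
                   res$predictions$id,
                   round(res$predictions$score_total * 10),
                   res$predictions$strand)
    bed_path <- file.path(config$outdir, "predictions.bed")
    writeLines(bed, bed_path)
    manifest <- c(manifest, predictions_bed = bed_path)
  }
  invisible(list(predictions = res$predictions, rejected = res$rejected,
                 stats = stats, manifest = manifest,
                 alignments = alignments))
}
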