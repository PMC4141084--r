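empty_run_files <- function(outdir) {
  write_results(predictions = data.frame(), rejected = data.frame(),
                stats = c(raw_reads = 0L), params_snapshot = list(seed = 1L),
                outdir = outdir)
}

test_that("a run with no predictions still writes all six files", {
  outdir <- withr::local_tempdir()
  manifest <- empty_run_files(outdir)
  expect_length(manifest, 6L)
  expect_true(all(file.exists(manifest)))
  for (nm in c("known_mir_expression", "novel_predictions",
               "rejected_candidates"))
    expect_length(readLines(manifest[[nm]]), 1L)  # header only
  expect_length(readLines(manifest[["mapping_stats"]]), 2L)
})

test_that("prediction tables are ordered by descending score", {
  sim <- run_small_sim(seed = 22L, n_hairpins = 3L, genome_len = 20000L)
  outdir <- withr::local_tempdir()
  res <- sim$res
  res$predictions$known_match <- NA_character_
  write_results(res$predictions, res$rejected, c(x = 1L), list(seed = 1L),
                outdir)
  tab <- read.delim(file.path(outdir, "novel_predictions.tsv"))
  expect_gte(nrow(tab), 2L)
  expect_true(all(diff(tab$score_total) <= 0))
})

test_that("predictions and rejections partition into the right files", {
  sim <- run_small_sim(seed = 23L, n_hairpins = 3L, genome_len = 20000L)
  res <- sim$res
  # force one prediction to look known
  known <- stats::setNames(chartr("Tt", "Uu", res$predictions$mature_seq[1]),
                           "mirX")
  res$predictions$known_match <- vapply(res$predictions$mature_seq,
                                        match_known, character(1),
                                        known = known, USE.NAMES = FALSE)
  outdir <- withr::local_tempdir()
  write_results(res$predictions, res$rejected, c(x = 1L), list(seed = 1L),
                outdir)
  known_tab <- read.delim(file.path(outdir, "known_mir_expression.tsv"))
  novel_tab <- read.delim(file.path(outdir, "novel_predictions.tsv"))
  rej_tab <- read.delim(file.path(outdir, "rejected_candidates.tsv"))
  expect_equal(nrow(known_tab) + nrow(novel_tab), nrow(res$predictions))
  expect_equal(nrow(known_tab), sum(!is.na(res$predictions$known_match)))
  expect_equal(nrow(rej_tab), nrow(res$rejected))
  expect_true(all(rej_tab$reason %in%
                    c("multibranch", "mature_position", "unpaired_mature",
                      "star_position", "short_loop", "inconsistent_reads",
                      "star_dominant", "no_reads", "low_score",
                      "superseded")))
})

test_that("text diagrams align reads at their precursor offsets", {
  pred <- list(id = "p1", chrom = "c1", start = 1001L, end = 1100L,
               strand = "+", score_total = 8.25,
               precursor_seq = strrep("ACGTG", 20L),
               dotbracket = strrep(".", 100L),
               mature_start = 21L, mature_len = 21L)
  members <- make_alignments("c1", start = c(1021L, 1051L), len = 21L,
                             count = c(57L, 3L),
                             seq = c(strrep("G", 21L), strrep("C", 21L)))
  lines <- render_hairpin_text(pred, members)
  expect_match(lines[1], "^>p1 c1:1001-1100\\(\\+\\)")
  # sequence line: mature uppercase, context lowercase, RNA alphabet
  seq_line <- lines[2]
  expect_equal(substr(seq_line, 21, 41),
               toupper(chartr("Tt", "Uu", substr(pred$precursor_seq, 21, 41))))
  expect_equal(substr(seq_line, 1, 20),
               tolower(chartr("Tt", "Uu", substr(pred$precursor_seq, 1, 20))))
  # first read line: 20 dots, 21 read bases, padding, then the copy count
  rd <- lines[4]
  expect_equal(substr(rd, 1, 20), strrep(".", 20))
  expect_equal(substr(rd, 21, 41), strrep("G", 21))
  expect_match(rd, " x57$")
  # reads sorted by copy count descending
  expect_match(lines[5], " x3$")
  # no reads: header + sequence + structure only
  expect_length(render_hairpin_text(pred, members[0, ]), 3L)
})

test_that("SVG mirrors the text grid and styles the mature red", {
  pred <- list(id = "p1", chrom = "c1", start = 1001L, end = 1100L,
               strand = "+", score_total = 8.25,
               precursor_seq = strrep("ACGTG", 20L),
               dotbracket = strrep(".", 100L),
               mature_start = 21L, mature_len = 21L)
  members <- make_alignments("c1", start = 1021L, len = 21L, count = 57L,
                             seq = strrep("G", 21L))
  path <- withr::local_tempfile(fileext = ".svg")
  render_hairpin_svg(pred, members, path)
  doc <- xml2::read_xml(path)
  texts <- xml2::xml_find_all(doc, "//*[local-name()='text']")
  grid <- plantmir:::.hairpin_grid(pred, members)
  expect_length(texts, length(grid))
  expect_identical(xml2::xml_text(texts), grid)
  reds <- xml2::xml_find_all(doc, "//*[local-name()='tspan'][@fill='red']")
  expect_length(reds, 1L)
  expect_identical(xml2::xml_text(reds), substr(grid[1], 21, 41))
})

test_that("result files are byte-identical across repeated writes", {
  sim <- run_small_sim(seed = 24L, n_hairpins = 2L, genome_len = 15000L)
  res <- sim$res
  res$predictions$known_match <- NA_character_
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_results(res$predictions, res$rejected, c(x = 1L), list(seed = 1L),
                out1)
  write_results(res$predictions, res$rejected, c(x = 1L), list(seed = 1L),
                out2)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
})
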