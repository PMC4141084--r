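# geometry helpers: perfect stem of `stem` pairs around a loop
perfect_stem_pairs <- function(stem, total) {
  lapply(seq_len(stem), function(i) c(i, total - i + 1L))
}

test_that("a clean stem-loop is parsed into arms, loop and mature arm", {
  # 30-bp stem, 25-nt loop, mature = first 21 nt
  total <- 85L
  fr <- fake_fold(total, perfect_stem_pairs(30L, total))
  cand <- list(mature_start = 1L, mature_len = 21L)
  ann <- parse_hairpin(cand, fr)
  expect_false(is_reject(ann))
  expect_equal(ann$arm5, c(1L, 30L))
  expect_equal(ann$terminal_loop, c(31L, 55L))
  expect_equal(ann$arm3, c(56L, 85L))
  expect_equal(ann$mature_arm, "five_prime")
  expect_equal(ann$paired_fraction_mature, 1)

  # mature on the 3' arm
  ann3 <- parse_hairpin(list(mature_start = 60L, mature_len = 21L), fr)
  expect_equal(ann3$mature_arm, "three_prime")
})

test_that("a mature straddling the terminal loop is rejected", {
  total <- 85L
  fr <- fake_fold(total, perfect_stem_pairs(30L, total))
  ann <- parse_hairpin(list(mature_start = 15L, mature_len = 21L), fr)
  expect_true(is_reject(ann))
  expect_equal(ann$reason, "mature_position")
  # mature outside any stem
  lone <- fake_fold(40L, perfect_stem_pairs(5L, 20L))
  out <- parse_hairpin(list(mature_start = 25L, mature_len = 10L), lone)
  expect_equal(out$reason, "mature_position")
})

test_that("two terminal loops inside the enclosing stem reject multibranch", {
  # outer pair (1,40) enclosing two separate inner hairpins
  rows <- c(list(c(1L, 40L), c(2L, 39L)),
            list(c(4L, 14L), c(5L, 13L)),   # first inner stem
            list(c(20L, 35L), c(21L, 34L))) # second inner stem
  fr <- fake_fold(40L, rows)
  ann <- parse_hairpin(list(mature_start = 1L, mature_len = 2L), fr)
  expect_true(is_reject(ann))
  expect_equal(ann$reason, "multibranch")
})

test_that("the star mirrors the mature with a 2-nt 3' overhang", {
  # perfect duplex: mature positions 1..21 pair with 35..55
  rows <- lapply(1:21, function(i) c(i, 56L - i))
  fr <- fake_fold(60L, rows)
  cand <- list(mature_start = 1L, mature_len = 21L)
  ann <- infer_star(parse_hairpin(cand, fr), fr)
  expect_equal(ann$star, c(37L, 57L))
  expect_equal(diff(ann$star) + 1L, 21L)
})

test_that("star inference is an involution on a perfect stem", {
  total <- 60L
  rows <- perfect_stem_pairs(28L, total)
  fr <- fake_fold(total, rows)
  params <- filter_params()
  m <- list(mature_start = 3L, mature_len = 20L)
  ann <- infer_star(parse_hairpin(m, fr), fr, params)
  star <- ann$star
  # treat the star as the mature of a second pass
  back <- infer_star(parse_hairpin(list(mature_start = star[1L],
                                        mature_len = star[2L] - star[1L] + 1L),
                                   fr), fr, params)
  expect_equal(back$star, c(m$mature_start, m$mature_start + 19L))
})

test_that("a 1-nt bulge in the mature changes star length by at most 1", {
  # partners: 1..10 -> 56-i ; 11 unpaired ; 12..21 -> 57-i (bulged duplex)
  rows <- c(lapply(1:10, function(i) c(i, 56L - i)),
            lapply(12:21, function(i) c(i, 57L - i)))
  fr <- fake_fold(60L, rows)
  ann <- infer_star(parse_hairpin(list(mature_start = 1L, mature_len = 21L),
                                  fr), fr)
  expect_false(is_reject(ann))
  expect_lte(abs((ann$star[2L] - ann$star[1L] + 1L) - 21L), 1L)
})

test_that("a mostly-unpaired mature is rejected", {
  # arm spans 1..35 but only 8 of the 21 mature bases pair (38% < 60%):
  # positions 9..21 sit in a large internal loop inside the arm
  rows <- lapply(c(1:8, 22:35), function(i) c(i, 101L - i))
  fr <- fake_fold(100L, rows)
  ann <- parse_hairpin(list(mature_start = 1L, mature_len = 21L), fr)
  expect_false(is_reject(ann))
  starred <- infer_star(ann, fr, filter_params())
  expect_true(is_reject(starred))
  expect_equal(starred$reason, "unpaired_mature")
})

test_that("the loop-span boundary is exactly the configured minimum", {
  mk <- function(loop_span) {
    # mature 1..21; star starts at 21 + loop_span + 1
    list(mature = c(1L, 21L), star = c(22L + loop_span, 42L + loop_span),
         loop_span = loop_span, mature_arm = "five_prime")
  }
  expect_true(check_loop(mk(25L), filter_params(min_loop = 25L)))
  expect_false(check_loop(mk(24L), filter_params(min_loop = 25L)))
  expect_true(check_loop(mk(0L), filter_params(min_loop = 0L)))
})

test_that("read consistency partitions copies and applies the strict 10% rule", {
  cand <- list(chrom = "c", strand = "+", start = 1001L, end = 1150L,
               sequence = strrep("A", 150L))
  ann <- list(mature = c(21L, 41L), star = c(101L, 121L),
              terminal_loop = c(50L, 95L))
  params <- filter_params()
  mk <- function(offsets, lens, counts) {
    make_alignments("c", start = 1000L + offsets, len = lens, count = counts)
  }
  # 91 copies on mature, 5 on star, 4 elsewhere: 4% inconsistent, passes
  a <- mk(c(21L, 101L, 60L), c(21L, 21L, 21L), c(91L, 5L, 4L))
  r <- read_consistency(a, cand, ann, params)
  expect_equal(r$ratio, 0.04)
  expect_true(r$pass)
  expect_equal(r$consistent_copies + r$inconsistent_copies, 100L)
  expect_equal(r$mature_copies, 91L)
  expect_equal(r$star_copies, 5L)

  # loop reads count against: 89 mature + 11 in the loop = 11% fails
  b <- mk(c(21L, 60L), c(21L, 21L), c(89L, 11L))
  rb <- read_consistency(b, cand, ann, params)
  expect_equal(rb$ratio, 0.11)
  expect_false(rb$pass)

  # all copies exactly on the mature
  rc <- read_consistency(mk(21L, 21L, 50L), cand, ann, params)
  expect_equal(rc$ratio, 0)
  expect_true(rc$pass)

  # exactly at the threshold fails (strict <)
  rd <- read_consistency(mk(c(21L, 60L), c(21L, 21L), c(90L, 10L)),
                         cand, ann, params)
  expect_equal(rd$ratio, 0.10)
  expect_false(rd$pass)

  # no overlapping copies is a reject
  expect_equal(read_consistency(mk(21L, 21L, 0L)[0, ], cand, ann,
                                params)$reason, "no_reads")
})

test_that("small positional drift is tolerated, star bonus needs position", {
  cand <- list(chrom = "c", strand = "+", start = 1001L, end = 1150L,
               sequence = strrep("A", 150L))
  ann <- list(mature = c(21L, 41L), star = c(101L, 121L))
  params <- filter_params(consistency_shift_tol = 3L)
  # mature read shifted by 3 nt is still consistent
  a <- make_alignments("c", start = 1024L, len = 21L, count = 10L)
  expect_equal(read_consistency(a, cand, ann, params)$mature_copies, 10L)
  # a short fragment inside the star region is consistent but carries no
  # star-positioned evidence
  frag <- make_alignments("c", start = c(1021L, 1106L), len = c(21L, 10L),
                          count = c(30L, 2L))
  r <- read_consistency(frag, cand, ann, params)
  expect_equal(r$consistent_copies, 32L)
  expect_equal(r$star_copies, 0L)
  # a full-length read at the star position does count
  full <- make_alignments("c", start = c(1021L, 1101L), len = 21L,
                          count = c(30L, 2L))
  expect_equal(read_consistency(full, cand, ann, params)$star_copies, 2L)
})

test_that("tightening thresholds never converts failures into passes", {
  cand <- list(chrom = "c", strand = "+", start = 1L, end = 150L,
               sequence = strrep("A", 150L))
  ann <- list(mature = c(21L, 41L), star = c(101L, 121L))
  a <- make_alignments("c", start = c(21L, 60L), len = 21L, count = c(92L, 8L))
  for (thr in c(0.02, 0.05, 0.08, 0.09)) {
    loose <- read_consistency(a, cand, ann,
                              filter_params(max_incon_ratio = thr))
    if (!loose$pass)
      expect_false(read_consistency(a, cand, ann,
                                    filter_params(max_incon_ratio = thr / 2))
                   $pass)
  }
  spans <- c(10L, 24L, 25L, 40L)
  results <- vapply(spans, function(ml)
    check_loop(list(loop_span = 25L), filter_params(min_loop = ml)),
    logical(1))
  expect_true(all(diff(rev(as.integer(results))) >= 0))  # monotone in min_loop
})
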