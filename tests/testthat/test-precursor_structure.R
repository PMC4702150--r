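test_that("dot-bracket parsing builds the symmetric partner table", {
  pm <- parse_dot_bracket("((((....))))")
  expect_equal(pm$partner[1:4], c(12L, 11L, 10L, 9L))
  expect_equal(pm$partner[9:12], c(4L, 3L, 2L, 1L))
  expect_true(all(is.na(pm$partner[5:8])))

  pm2 <- parse_dot_bracket("...")
  expect_true(all(is.na(pm2$partner)))

  expect_error(parse_dot_bracket("((("), "unclosed")
  expect_error(parse_dot_bracket("))"), "position 1")
  expect_error(parse_dot_bracket("(.[)"), "position 3")
})

test_that("parsing then serializing reproduces the structure string", {
  set.seed(31)
  for (i in 1:20) {
    hp <- perfect_hairpin(sample(10:40, 1), sample(3:8, 1),
                          sample(0:10, 1), sample(0:10, 1))
    expect_identical(as.character(parse_dot_bracket(hp$structure)),
                     hp$structure)
  }
  # partner table symmetry on random structures
  hp <- perfect_hairpin(30, 5, 4, 4)
  pm <- parse_dot_bracket(hp$structure)
  paired <- which(!is.na(pm$partner))
  expect_equal(pm$partner[pm$partner[paired]], paired)
})

test_that("bracket coverage requires half the locus paired in one direction", {
  # 21-nt locus fully on a 30-bp arm: coverage 1, all "("
  db <- paste0(strrep(".", 20), strrep("(", 30), "....", strrep(")", 30),
               strrep(".", 20))
  pm <- parse_dot_bracket(db)
  r <- bracket_coverage_screen(pm, 21, 41)
  expect_true(r$pass)
  expect_equal(r$coverage, 1)
  expect_equal(r$direction, "(")

  # locus [10, 30]: 11 unpaired flank positions, 10 paired -> 0.476 fails
  r2 <- bracket_coverage_screen(pm, 10, 30)
  expect_equal(r2$coverage, 10 / 21)
  expect_false(r2$pass)

  # locus straddling the loop has both bracket directions -> fail
  db3 <- paste0(strrep("(", 10), "....", strrep(")", 10))
  r3 <- bracket_coverage_screen(parse_dot_bracket(db3), 3, 23)
  expect_true(r3$coverage >= 0.5)
  expect_equal(r3$direction, "mixed")
  expect_false(r3$pass)

  expect_error(bracket_coverage_screen(pm, 90, 120), "out of structure range")
})

test_that("stem-loop detection finds the hairpin hosting the locus", {
  hp <- perfect_hairpin(30, 6, 10, 10)
  pm <- parse_dot_bracket(hp$structure)
  # miRNA on the 5' arm (positions 13..33 inside arm 11..40)
  sl <- detect_stem_loop(pm, 13, 33, min_stem_pairs = 15)
  expect_s3_class(sl, "stem_loop")
  expect_equal(sl$arm5, c(11, 40))
  expect_equal(sl$arm3, c(47, 76))
  expect_equal(sl$loop, c(41, 46))
  expect_equal(sl$n_pairs, 30L)
  expect_true(sl$contains_mir)
  expect_equal(sl$side, "5p")

  # same locus found from the 3' arm
  sl3 <- detect_stem_loop(pm, 50, 70, min_stem_pairs = 15)
  expect_equal(sl3$side, "3p")
  expect_true(sl3$contains_mir)

  # locus straddling the loop -> none
  expect_null(detect_stem_loop(pm, 35, 55, min_stem_pairs = 15))

  # two short hairpins of 8 bp each never reach 15 stem pairs
  short <- paste0(strrep("(", 8), "....", strrep(")", 8))
  db2 <- paste0(short, "..", short)
  pm2 <- parse_dot_bracket(db2)
  expect_null(detect_stem_loop(pm2, 2, 7, min_stem_pairs = 15))
  expect_s3_class(detect_stem_loop(pm2, 2, 7, min_stem_pairs = 5), "stem_loop")
})

test_that("stem-loop helices extend across small bulges but not branches", {
  # 10 pairs, a 3-nt interior bulge on the 3' side, 10 more pairs
  db <- paste0(strrep("(", 20), "....", strrep(")", 10), "...", strrep(")", 10))
  pm <- parse_dot_bracket(db)
  sl <- detect_stem_loop(pm, 2, 6, min_stem_pairs = 15)
  expect_equal(sl$n_pairs, 20L)
  # with tolerance below the bulge size only the inner helix is collected
  expect_null(detect_stem_loop(pm, 2, 6, min_stem_pairs = 15, max_gap = 2))

  # branched (multiloop) region is not a simple stem-loop
  db_branch <- paste0("((((", "((((....))))", "((((....))))", "))))")
  pmb <- parse_dot_bracket(db_branch)
  expect_null(detect_stem_loop(pmb, 1, 4, min_stem_pairs = 2))
})

test_that("star locus follows the 2-nt 3'-overhang geometry on perfect stems", {
  hp <- perfect_hairpin(40, 6, 10, 10)
  pm <- parse_dot_bracket(hp$structure)
  s <- 15L; e <- 35L # mature miRNA on the 5' arm
  dc <- find_star(pm, s, e, transcript_seq = hp$sequence)
  # independent check from the closed-form partner formula
  expect_equal(dc$star[1], hp$partner_formula(e - 2L))
  expect_equal(dc$star[2], hp$partner_formula(s) + 2L)
  expect_equal(unname(dc$overhangs), c(2, 2))
  # duplex symmetry: the star of the star is the original mature locus
  back <- find_star(pm, dc$star[1], dc$star[2], transcript_seq = hp$sequence)
  expect_equal(back$star, c(s, e))
})

test_that("bulged duplex boundaries and overlapping geometries are rejected", {
  # position e-2 unpaired: put a bulge in the 5' arm at the right spot
  db <- paste0(strrep(".", 5), strrep("(", 20), ".", strrep("(", 10), "....",
               strrep(")", 30), strrep(".", 5))
  pm <- parse_dot_bracket(db)
  # locus [6, 26]: e-2 = 24 is paired, s = 6 paired -> fine
  expect_s3_class(find_star(pm, 6, 26, transcript_seq = strrep("A", pm$length)),
                  "duplex_call")
  # locus [8, 28]: e-2 = 26 is the bulged dot -> none
  expect_null(find_star(pm, 8, 28))

  # a locus spanning the loop would produce an overlapping "star" -> none
  hp <- perfect_hairpin(25, 4, 0, 6)
  pm2 <- parse_dot_bracket(hp$structure)
  expect_null(find_star(pm2, 20, 40))
})

test_that("measured overhangs reject 1-nt and 3-nt constructions", {
  hp <- perfect_hairpin(40, 6, 10, 10)
  pm <- parse_dot_bracket(hp$structure)
  s <- 15L; e <- 35L
  proper <- c(hp$partner_formula(e - 2L), hp$partner_formula(s) + 2L)
  expect_equal(unname(duplex_overhangs(pm, c(s, e), proper)), c(2, 2))
  one_nt <- proper + c(0L, -1L)   # star 3' end trimmed by 1
  expect_equal(unname(duplex_overhangs(pm, c(s, e), one_nt)[2]), 1)
  three_nt <- proper + c(0L, 1L)
  expect_equal(unname(duplex_overhangs(pm, c(s, e), three_nt)[2]), 3)
  # shifting the star 5' end breaks the mature-side overhang
  shift5 <- proper + c(2L, 0L)
  expect_false(identical(unname(duplex_overhangs(pm, c(s, e), shift5)[1]), 2))
})

test_that("star detection reflects library content without discarding geometry", {
  hp <- perfect_hairpin(40, 6, 10, 10)
  pm <- parse_dot_bracket(hp$structure)
  dc0 <- find_star(pm, 15, 35, transcript_seq = hp$sequence)
  star_seq <- dc0$star_seq
  libs_with <- make_libs(setNames(c(100, 7), c("GGGGGGGGGGGGGGGGGGGGG", star_seq)))
  libs_without <- make_libs(setNames(100, "GGGGGGGGGGGGGGGGGGGGG"))
  dc1 <- find_star(pm, 15, 35, transcript_seq = hp$sequence, libs = libs_with)
  expect_true(dc1$star_detected)
  expect_equal(length(dc1$star_rpm), 8L)
  dc2 <- find_star(pm, 15, 35, transcript_seq = hp$sequence, libs = libs_without)
  expect_s3_class(dc2, "duplex_call")  # geometry kept, star unconfirmed
  expect_false(dc2$star_detected)
})

test_that("random perfect hairpins always pass coverage and the duplex rule", {
  set.seed(77)
  for (i in 1:100) {
    arm <- sample(25:60, 1)
    loop <- sample(4:12, 1)
    flank <- sample(5:20, 1)
    hp <- perfect_hairpin(arm, loop, flank, flank)
    pm <- parse_dot_bracket(hp$structure)
    offset <- sample.int(arm - 21L, 1)
    s <- flank + offset + 1L
    e <- s + 20L
    cov <- bracket_coverage_screen(pm, s, e)
    expect_true(cov$pass)
    expect_equal(cov$coverage, 1)
    dc <- find_star(pm, s, e, transcript_seq = hp$sequence)
    expect_equal(unname(dc$overhangs), c(2, 2))
    back <- find_star(pm, dc$star[1], dc$star[2], transcript_seq = hp$sequence)
    expect_equal(back$star, c(s, e))
  }
})
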