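mk_deg <- function(rows, organ = "stem", total = 1e6) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript = r[[1]], pos = r[[2]], sequence = r[[3]],
               count = r[[4]], stringsAsFactors = FALSE)
  }))
  degradome_library(df, organ = organ, total = total)
}

# distinct valid tag sequences, deterministically indexed
tag_n <- local({
  bases <- c("A", "C", "G", "T")
  function(i) {
    idx <- c(i %% 4, (i %/% 4) %% 4, (i %/% 16) %% 4, (i %/% 64) %% 4) + 1
    paste0(strrep("G", 16), paste(bases[idx], collapse = ""))
  }
})

test_that("processing evidence matches tag 5' ends at duplex boundaries", {
  deg <- mk_deg(list(
    list("pre1", 121L, tag_n(1), 50),  # at locus end + 1
    list("pre1", 123L, tag_n(2), 50),  # 2 nt off
    list("pre1", 80L, tag_n(3), 30)    # at locus start
  ))
  loci <- data.frame(transcript = "pre1", start = 80L, end = 120L,
                     label = "mir*")
  ev <- processing_evidence(deg, loci, tolerance = 0)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$end_type, c("5p", "3p"))
  expect_equal(ev$rpm[ev$end_type == "3p"], 50)
  # tolerance widens the window
  ev2 <- processing_evidence(deg, loci, tolerance = 2)
  expect_equal(sum(ev2$end_type == "3p"), 2L)
  # tag at e+3 with tolerance 0 is not evidence
  deg3 <- mk_deg(list(list("pre1", 124L, tag_n(4), 10)))
  expect_equal(nrow(processing_evidence(deg3, loci)), 0L)
})

test_that("complementarity scoring penalizes the miRNA core twice", {
  mir <- "TGACAGAAGAGAGTGAGCACA" # 21 nt
  perfect <- revcomp_chr(mir)
  expect_equal(score_site(mir, perfect)$score, 0)

  # U:G wobble at miRNA position 14 (outside the 2-13 core): 0.5
  stopifnot(substr(mir, 14, 14) == "T")
  win <- strsplit(perfect, "")[[1]]
  win[21 - 14 + 1] <- "G"
  s <- score_site(mir, paste(win, collapse = ""))
  expect_equal(s$score, 0.5)
  expect_equal(substr(s$alignment, 14, 14), "o")

  # mismatch at position 5 (core): doubled to 2.0
  win2 <- strsplit(perfect, "")[[1]]
  mir5 <- substr(mir, 5, 5)
  win2[21 - 5 + 1] <- mir5 # same base as the miRNA cannot pair
  s2 <- score_site(mir, paste(win2, collapse = ""))
  expect_equal(s2$score, 2)
  expect_equal(substr(s2$alignment, 5, 5), ".")

  expect_error(score_site(mir, "ACGT"), "length")
})

test_that("the scanner reports the planted complementary window", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tx <- paste0(rand_nt(100), revcomp_chr(mir), rand_nt(100))
  sites <- scan_targets(mir, tx, transcript = "t1", threshold = 4)
  hit <- Filter(function(s) s$window[1] == 101, sites)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$score, 0)
  # cleavage position opposite miRNA nt 10
  expect_equal(hit[[1]]$cleavage_pos, 101 + 21 - 10)
})

test_that("rule 1 compares site and surrounding signature averages at 5-fold", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tx_site <- list(transcript = "t1", window = c(101, 121),
                  cleavage_pos = 112, mir_seq = mir)
  # site signatures 40 and 60 RPM (avg 50); elsewhere 5,5,10,20 (avg 10)
  deg <- mk_deg(list(
    list("t1", 112L, tag_n(1), 40), list("t1", 112L, tag_n(2), 60),
    list("t1", 10L, tag_n(3), 5), list("t1", 30L, tag_n(4), 5),
    list("t1", 50L, tag_n(5), 10), list("t1", 70L, tag_n(6), 20)))
  cl <- validate_cleavage(tx_site, list(deg))
  expect_equal(cl$per_library$avg_site, 50)
  expect_equal(cl$per_library$avg_surround, 10)
  expect_true(cl$per_library$rule1)   # boundary inclusive: 50 >= 5 x 10
  expect_true(cl$supported)

  deg2 <- mk_deg(list(
    list("t1", 112L, tag_n(1), 49),
    list("t1", 10L, tag_n(3), 5), list("t1", 30L, tag_n(4), 5),
    list("t1", 50L, tag_n(5), 10), list("t1", 70L, tag_n(6), 20)))
  cl2 <- validate_cleavage(tx_site, list(deg2))
  expect_false(cl2$per_library$rule1)
  expect_false(cl2$supported)
})

test_that("rule 2 ranks the site signature among the transcript's top 12", {
  tx_site <- list(transcript = "t1", window = c(101, 121),
                  cleavage_pos = 112, mir_seq = "x")
  build <- function(n_decoys) {
    rows <- list(list("t1", 112L, tag_n(99), 50))
    for (i in seq_len(n_decoys)) {
      rows[[length(rows) + 1L]] <- list("t1", 200L + i, tag_n(i), 100 + i)
    }
    mk_deg(rows)
  }
  # brute-force rank oracle: position of the site count in the sorted counts
  brute_rank <- function(site_count, all_counts) {
    sum(sort(all_counts, decreasing = TRUE) > site_count) + 1L
  }
  expect_equal(brute_rank(50, c(50, 100 + 1:13)), 14L)
  expect_equal(brute_rank(50, c(50, 100 + 1:11)), 12L)

  cl13 <- validate_cleavage(tx_site, list(build(13)))
  expect_false(cl13$per_library$rule2)
  cl11 <- validate_cleavage(tx_site, list(build(11)))
  expect_true(cl11$per_library$rule2)
  # ties share the better rank: a 12th signature equal to the site passes
  deg_tie <- mk_deg(c(list(list("t1", 112L, tag_n(99), 100)),
                      lapply(1:12, function(i) list("t1", 200L + i, tag_n(i), 100))))
  expect_true(validate_cleavage(tx_site, list(deg_tie))$per_library$rule2)
})

test_that("rule 3 accepts cleavage opposite miRNA nt 10 or 11 only", {
  tx_site <- list(transcript = "t1", window = c(101, 121),
                  cleavage_pos = 112, mir_seq = "x")
  at <- function(p) mk_deg(list(list("t1", p, tag_n(1), 50),
                                list("t1", 10L, tag_n(2), 1)))
  expect_true(validate_cleavage(tx_site, list(at(112L)))$per_library$rule3)  # nt 10
  expect_true(validate_cleavage(tx_site, list(at(111L)))$per_library$rule3)  # nt 11
  cl9 <- validate_cleavage(tx_site, list(at(113L)))                          # nt 9
  expect_false(cl9$per_library$rule3)
  expect_false(cl9$supported)
})

test_that("validation is monotone in fold and top_k and ignores library order", {
  tx_site <- list(transcript = "t1", window = c(101, 121),
                  cleavage_pos = 112, mir_seq = "x")
  set.seed(5)
  degs <- lapply(c("root", "stem", "leaf", "flower"), function(o) {
    rows <- list(list("t1", 112L, tag_n(50), sample(20:80, 1)))
    for (i in 1:6) rows[[length(rows) + 1L]] <-
      list("t1", 10L * i, tag_n(i), sample(1:30, 1))
    mk_deg(rows, organ = o)
  })
  base <- validate_cleavage(tx_site, degs, fold = 5, top_k = 12)
  stricter <- list(validate_cleavage(tx_site, degs, fold = 8, top_k = 12),
                   validate_cleavage(tx_site, degs, fold = 5, top_k = 3))
  for (s in stricter) {
    expect_true(all(base$per_library$overall | !s$per_library$overall))
  }
  perm <- validate_cleavage(tx_site, rev(degs), fold = 5, top_k = 12)
  reord <- perm$per_library[match(base$per_library$organ, perm$per_library$organ), ]
  expect_equal(reord$avg_site, base$per_library$avg_site)
  expect_equal(reord$avg_surround, base$per_library$avg_surround)
})

test_that("regulation specificity distinguishes organ-, vegetative- and constitutive", {
  fake_call <- function(verdicts) {
    structure(list(
      site = list(transcript = "t1", cleavage_pos = 112, mir_seq = "m"),
      per_library = data.frame(organ = c("root", "stem", "leaf", "flower"),
                               overall = verdicts),
      supported = any(verdicts)), class = "cleavage_call")
  }
  cls <- list(fake_call(c(FALSE, FALSE, FALSE, TRUE)),  # flower only
              fake_call(c(FALSE, TRUE, TRUE, FALSE)),   # leaf + stem
              fake_call(c(TRUE, TRUE, TRUE, TRUE)))     # everywhere
  sp <- organ_specificity_of_regulation(cls)
  expect_equal(sp$specific_organ[1], "flower")
  expect_true(sp$organ_specific[1])
  expect_false(sp$vegetative_specific[1])
  expect_false(sp$organ_specific[2])
  expect_true(sp$vegetative_specific[2])
  expect_true(sp$constitutive[3])
  expect_false(sp$vegetative_specific[3])
})

test_that("a transcript without degradome placements yields all-false verdicts", {
  tx_site <- list(transcript = "t_absent", window = c(101, 121),
                  cleavage_pos = 112, mir_seq = "x")
  deg <- mk_deg(list(list("other", 5L, tag_n(1), 10)))
  cl <- validate_cleavage(tx_site, list(deg))
  expect_false(any(cl$per_library[, c("rule1", "rule2", "rule3")]))
  expect_false(cl$supported)
})
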