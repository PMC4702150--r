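test_that("collapsed sRNA input aggregates duplicates and reads both dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ACGTACGTACGTACGTACGTA\t7", "ACGTACGTACGTACGTACGTA\t3"), tsv)
  lib <- read_collapsed_srna(tsv, "root", "1")
  expect_equal(unname(lib$counts[["ACGTACGTACGTACGTACGTA"]]), 10)
  expect_equal(lib$total, 10)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1_5", "TGACGT"), fa)
  lib2 <- read_collapsed_srna(fa, "root", "1")
  expect_equal(unname(lib2$counts[["TGACGT"]]), 5)

  # dash-delimited headers and U-space sequences are accepted too
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1-12", "UGACGU"), fa2)
  expect_equal(unname(read_collapsed_srna(fa2, "x", "1")$counts[["TGACGT"]]), 12)
})

test_that("malformed collapsed input is rejected with a located error", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1_x", "TGACGT"), fa)
  expect_error(read_collapsed_srna(fa, "root", "1"), "record 1")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ACGT\t3", "ACGA\t2.5"), tsv)
  expect_error(read_collapsed_srna(tsv, "root", "1"), "line 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_collapsed_srna(empty, "root", "1"), "empty library")
})

test_that("RPM follows the raw-count / library-total formula", {
  lib <- srna_library(c(ACGTACGTACGTACGTACGTA = 50), "root", "1", total = 2e6)
  expect_identical(unname(normalize_rpm(lib, "ACGTACGTACGTACGTACGTA")), 25)
  expect_identical(unname(normalize_rpm(lib, "TTTTTTTTTTTTTTTTTTTTT")), 0)

  lib2 <- srna_library(c(AAAAAAAAAAAAAAAAAAAAA = 1, CCCCCCCCCCCCCCCCCCCCC = 3),
                       "root", "1")
  expect_identical(unname(normalize_rpm(lib2, "AAAAAAAAAAAAAAAAAAAAA")), 250000)
})

test_that("library RPM values sum to one million", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    counts <- setNames(sample(1:500, n, replace = TRUE),
                       vapply(seq_len(n), function(i) rand_nt(21L), ""))
    lib <- srna_library(counts, "root", "1")
    expect_equal(sum(normalize_rpm(lib)), 1e6, tolerance = 1e-6)
  }
})

test_that("RPKM matches the reads / (million mapped x kilobase) formula", {
  m <- matrix(c(100, 9999900), 2, 1,
              dimnames = list(c("t1", "pad"), "root_1"))
  r <- compute_rpkm(m, c(t1 = 1000, pad = 5000))
  expect_equal(unname(r["t1", 1]), 10)

  m2 <- matrix(c(5, 999995), 2, 1, dimnames = list(c("t1", "pad"), "s"))
  expect_equal(unname(compute_rpkm(m2, c(t1 = 500, pad = 1000))["t1", 1]), 10)

  m3 <- matrix(c(0, 10), 2, 1, dimnames = list(c("t1", "t2"), "s"))
  expect_equal(unname(compute_rpkm(m3, c(t1 = 500, t2 = 100))["t1", 1]), 0)

  expect_error(compute_rpkm(m3, c(t1 = 500)), "t2")
  m4 <- matrix(0, 1, 1, dimnames = list("t1", "s"))
  expect_error(compute_rpkm(m4, c(t1 = 100)), "zero mapped-read total")
})

test_that("RPKM is invariant under uniform count scaling within a sample", {
  set.seed(4)
  m <- matrix(sample(1:1000, 40), 10, 4,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  lens <- setNames(sample(200:2000, 10), paste0("t", 1:10))
  expect_equal(compute_rpkm(m * 7, lens), compute_rpkm(m, lens),
               ignore_attr = TRUE)
})

test_that("perfect placement reports every sense occurrence 1-based inclusive", {
  cat <- transcript_catalog(c(t1 = "TTACGTACGTT"))
  hits <- map_perfect("ACGTACG", cat)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 9L)

  expect_equal(nrow(map_perfect("GGGGGGG", cat)), 0L)

  cat2 <- transcript_catalog(c(t1 = "AACGTAACGTA"))
  hits2 <- map_perfect("AACGTA", cat2)
  expect_equal(hits2$start, c(1L, 6L))
})

test_that("perfect placement agrees with a naive substring scan", {
  naive_scan <- function(query, seqs) {
    out <- NULL
    for (id in names(seqs)) {
      s <- seqs[[id]]
      L <- nchar(query)
      for (i in seq_len(nchar(s) - L + 1L)) {
        if (substr(s, i, i + L - 1L) == query) {
          out <- rbind(out, data.frame(transcript = id, start = i,
                                       end = i + L - 1L))
        }
      }
    }
    if (is.null(out)) data.frame(transcript = character(), start = integer(),
                                 end = integer()) else out
  }
  set.seed(99)
  for (case in 1:100) {
    seqs <- setNames(
      vapply(1:3, function(i) rand_nt(sample(40:120, 1)), ""),
      paste0("t", 1:3))
    # half the cases plant the query to guarantee hits
    q <- rand_nt(6L)
    if (case %% 2 == 0) {
      host <- sample(3, 1)
      pos <- sample(nchar(seqs[[host]]) - 6L, 1)
      substr(seqs[[host]], pos, pos + 5L) <- q
    }
    got <- map_perfect(q, transcript_catalog(seqs))
    want <- naive_scan(q, seqs)
    want <- want[order(want$transcript, want$start), , drop = FALSE]
    expect_equal(got[, c("transcript", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("transcript catalogs normalize alphabet and reject bad input", {
  cat <- transcript_catalog(c(t1 = "acguACGU"))
  expect_identical(unclass(cat)[["t1"]], "ACGTACGT")
  expect_error(transcript_catalog(c(t1 = "ACGT", t1 = "ACGT")), "unique")
  expect_error(transcript_catalog(c(t1 = "ACXT")), "alphabet|characters")
  expect_error(transcript_catalog(setNames("ACGT", "")), "identifier")
})
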