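#' Map library small RNAs onto the arms of a long stem
#'
#' Collects every distinct library sequence of length `min_len`..`max_len`
#' with a perfect sense placement fully contained in one arm of the stem-loop
#' (reads overlapping the loop or arm boundaries are excluded). Placements
#' are deduplicated by coordinates.
#'
#' @param libs List of [srna_library()].
#' @param transcript_seq Precursor transcript sequence.
#' @param stem A [detect_stem_loop()] call.
#' @param min_len,max_len Read length bounds (defaults 18 and 26 nt).
#' @return `data.frame(sequence, start, end, arm, count_total)` sorted by
#'   start; `count_total` sums raw counts over all libraries.
#' @export
map_srnas_to_stem <- function(libs, transcript_seq, stem,
                              min_len = 18L, max_len = 26L) {
  stopifnot(inherits(stem, "stem_loop"))
  transcript_seq <- .normalize_seq(transcript_seq)
  seqs <- unique(unlist(lapply(libs, function(l) names(l$counts))))
  seqs <- seqs[nchar(seqs) >= min_len & nchar(seqs) <= max_len]
  # cheap prefilter: only sequences occurring anywhere in the transcript
  seqs <- seqs[vapply(seqs, function(q) grepl(q, transcript_seq, fixed = TRUE),
                      TRUE)]
  totals <- vapply(seqs, function(q) {
    sum(vapply(libs, function(l) {
      x <- l$counts[q]
      if (is.na(x)) 0 else as.numeric(x)
    }, 0))
  }, 0)
  names(totals) <- seqs
  cat_one <- transcript_catalog(setNames(transcript_seq, "tx"))
  rows <- lapply(seqs, function(q) {
    hits <- map_perfect(q, cat_one)
    if (nrow(hits) == 0L) return(NULL)
    in5 <- hits$start >= stem$arm5[1L] & hits$end <= stem$arm5[2L]
    in3 <- hits$start >= stem$arm3[1L] & hits$end <= stem$arm3[2L]
    hits <- hits[in5 | in3, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    data.frame(sequence = q, start = hits$start, end = hits$end,
               arm = ifelse(hits$start >= stem$arm3[1L], "3p", "5p"),
               count_total = totals[[q]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    sequence = character(), start = integer(), end = integer(),
    arm = character(), count_total = numeric()))))
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect phase-distributed small-RNA blocks on a stem
#'
#' Chains mapped loci head-to-tail on the arm carrying more loci (next start
#' = previous end + 1, within `tol` nucleotides), then attempts a duplex
#' partner call for every chained locus via the 2-nt 3'-overhang geometry of
#' [find_star()]. Chains of at least `min_chain` loci are reported as phased
#' blocks; loci whose geometric partner sequence is undetected in the
#' libraries stay in the block flagged as singletons.
#'
#' @param loci Output of [map_srnas_to_stem()].
#' @param pm Pairing map of the transcript.
#' @param transcript_seq Transcript sequence.
#' @param libs Libraries used for partner detection.
#' @param min_chain Minimum chained loci per reported block (default 2).
#' @param tol Adjacency tolerance in nt (default 0 = exact head-to-tail).
#' @return List of `phased_block` objects; each holds `loci` (a data.frame
#'   with partner coordinates, overhangs and `duplex` flag), `n_duplexes`
#'   and `n_singletons`.
#' @export
find_phased_blocks <- function(loci, pm, transcript_seq, libs,
                               min_chain = 2L, tol = 0L) {
  if (nrow(loci) == 0L) return(list())
  arm_counts <- table(factor(loci$arm, levels = c("5p", "3p")))
  seed_arm <- if (arm_counts[["3p"]] > arm_counts[["5p"]]) "3p" else "5p"
  seed <- loci[loci$arm == seed_arm, , drop = FALSE]
  seed <- seed[order(seed$start), , drop = FALSE]
  if (nrow(seed) == 0L) return(list())

  gaps <- seed$start[-1L] - seed$end[-nrow(seed)] - 1L
  chain_id <- cumsum(c(1L, as.integer(abs(gaps) > tol)))
  blocks <- list()
  for (cid in unique(chain_id)) {
    ch <- seed[chain_id == cid, , drop = FALSE]
    if (nrow(ch) < min_chain) next
    partner_start <- partner_end <- rep(NA_integer_, nrow(ch))
    oh_mir <- oh_star <- rep(NA_real_, nrow(ch))
    duplex <- logical(nrow(ch))
    partner_seq <- rep(NA_character_, nrow(ch))
    for (k in seq_len(nrow(ch))) {
      dc <- find_star(pm, ch$start[k], ch$end[k],
                      transcript_seq = transcript_seq, libs = libs)
      if (is.null(dc)) next
      partner_start[k] <- dc$star[1L]
      partner_end[k] <- dc$star[2L]
      oh_mir[k] <- dc$overhangs[["mir3"]]
      oh_star[k] <- dc$overhangs[["star3"]]
      partner_seq[k] <- dc$star_seq
      duplex[k] <- isTRUE(dc$star_detected)
    }
    df <- cbind(ch, data.frame(partner_start = partner_start,
                               partner_end = partner_end,
                               overhang_mir3 = oh_mir,
                               overhang_star3 = oh_star,
                               partner_sequence = partner_seq,
                               duplex = duplex))
    rownames(df) <- NULL
    blocks[[length(blocks) + 1L]] <- structure(
      list(arm = seed_arm, loci = df,
           n_duplexes = sum(duplex),
           n_singletons = sum(!duplex)),
      class = "phased_block")
  }
  blocks
}

#' @export
print.phased_block <- function(x, ...) {
  cat(sprintf("phased block on %s arm: %d loci [%d, %d], %d duplexes, %d singletons\n",
              x$arm, nrow(x$loci), min(x$loci$start), max(x$loci$end),
              x$n_duplexes, x$n_singletons))
  invisible(x)
}
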