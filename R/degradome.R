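#' Construct a degradome (PARE) library
#'
#' A degradome library holds 5'-tag counts positioned on transcripts: each
#' placement is a perfect sense match of a tag whose 5' end marks the 5' end
#' of an uncapped RNA fragment (a candidate cleavage position).
#'
#' @param placements `data.frame(transcript, pos, sequence, count)`: `pos` is
#'   the 1-based transcript position of the tag's 5' end; `count` the raw
#'   read count of the tag (repeated placements of one tag carry the same
#'   count).
#' @param organ Organ label.
#' @param total Library size used for RPM normalization; defaults to the sum
#'   of distinct tag counts (each tag counted once). The raw total of the
#'   sequencing library may be supplied instead.
#' @return Object of class `degradome_library` with fields `organ`, `tags`
#'   (named counts per distinct tag), `placements` and `total`.
#' @export
degradome_library <- function(placements, organ, total = NULL) {
  need <- c("transcript", "pos", "sequence", "count")
  if (!all(need %in% names(placements))) {
    stop("placements need columns: ", paste(need, collapse = ", "))
  }
  placements$sequence <- .normalize_seq(placements$sequence)
  if (any(placements$pos < 1L)) stop("placement positions must be >= 1")
  if (any(placements$count < 0)) stop("tag counts must be non-negative")
  tag_df <- unique(placements[, c("sequence", "count")])
  if (anyDuplicated(tag_df$sequence)) {
    stop("a tag sequence carries inconsistent counts across placements")
  }
  tags <- setNames(tag_df$count, tag_df$sequence)
  if (is.null(total)) total <- sum(tags)
  if (total <= 0) stop("empty degradome library")
  placements <- placements[order(placements$transcript, placements$pos), , drop = FALSE]
  rownames(placements) <- NULL
  structure(list(organ = as.character(organ), tags = tags,
                 placements = placements, total = total),
            class = "degradome_library")
}

#' @export
print.degradome_library <- function(x, ...) {
  cat(sprintf("degradome library (%s): %d distinct tags, %d placements, total %s\n",
              x$organ, length(x$tags), nrow(x$placements),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Read / write degradome placements as TSV
#' (columns: transcript, pos, sequence, count)
#'
#' @param path File path.
#' @param organ Organ label.
#' @param total Optional raw library total (see [degradome_library()]).
#' @export
read_degradome <- function(path, organ, total = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  degradome_library(df, organ, total = total)
}

#' @rdname read_degradome
#' @param deg A `degradome_library`.
#' @export
write_degradome <- function(deg, path) {
  write.table(deg$placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Degradome evidence for precursor processing at duplex ends
#'
#' Dicer-like 1 excision of a duplex leaves uncapped fragments whose 5' ends
#' sit at the locus 5' end (`start`) and immediately downstream of the locus
#' 3' end (`end + 1`). For each supplied locus, tags whose 5' ends fall at
#' those positions (within `tolerance` nt) are reported with their RPM.
#'
#' @param deg A [degradome_library()].
#' @param loci `data.frame(transcript, start, end)` with optional `label`.
#' @param tolerance Positional slack in nt (default 0).
#' @return `data.frame(label, transcript, end_type, expected_pos, pos,
#'   sequence, count, rpm)`; zero rows when nothing matches.
#' @export
processing_evidence <- function(deg, loci, tolerance = 0L) {
  stopifnot(inherits(deg, "degradome_library"))
  if (is.null(loci$label)) loci$label <- paste0("locus", seq_len(nrow(loci)))
  out <- list()
  for (k in seq_len(nrow(loci))) {
    pl <- deg$placements[deg$placements$transcript == loci$transcript[k], , drop = FALSE]
    if (nrow(pl) == 0L) next
    for (endt in c("5p", "3p")) {
      exp_pos <- if (endt == "5p") loci$start[k] else loci$end[k] + 1L
      hit <- pl[abs(pl$pos - exp_pos) <= tolerance, , drop = FALSE]
      if (nrow(hit) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        label = loci$label[k], transcript = loci$transcript[k],
        end_type = endt, expected_pos = exp_pos,
        pos = hit$pos, sequence = hit$sequence, count = hit$count,
        rpm = 1e6 * hit$count / deg$total, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(label = character(), transcript = character(),
                      end_type = character(), expected_pos = integer(),
                      pos = integer(), sequence = character(),
                      count = numeric(), rpm = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Score miRNA:target complementarity over a gapless window
#'
#' Plumbing scorer standing in for an external target-prediction step (a
#' user-supplied site list may be used instead). The miRNA (5'->3') is
#' aligned antiparallel to a same-length target window (5'->3'): miRNA
#' position `i` faces target window position `L - i + 1`. Penalties per
#' miRNA position: mismatch 1.0, G:U wobble 0.5, doubled at positions 2-13
#' (the functionally critical core). A site is reported as passing when the
#' total score is at or below `threshold`.
#'
#' @param mir_seq Mature miRNA sequence (5'->3').
#' @param window_seq Target window, same length, sense strand (5'->3').
#' @param transcript,window_start Optional placement of the window on a
#'   transcript; enables the cleavage-position fields.
#' @param threshold Maximum score for a reported site (default 4.0).
#' @return Object of class `target_site`: list with `score`, `alignment`
#'   (per-position `|` match, `o` wobble, `.` mismatch, miRNA 5'->3'),
#'   `pass`, and, when placed, `window = c(start, end)` and `cleavage_pos`
#'   (target position opposite miRNA nt 10).
#' @export
score_site <- function(mir_seq, window_seq, transcript = NA_character_,
                       window_start = NA_integer_, threshold = 4) {
  mir <- strsplit(.normalize_seq(mir_seq), "")[[1L]]
  win <- strsplit(.normalize_seq(window_seq), "")[[1L]]
  L <- length(mir)
  if (length(win) != L) stop("target window must have the miRNA's length (gapless mode)")
  states <- character(L)
  score <- 0
  for (i in seq_len(L)) {
    t <- win[L - i + 1L]
    m <- mir[i]
    pen <- if (t == .COMPLEMENT[[m]]) {
      states[i] <- "|"; 0
    } else if ((m == "G" && t == "T") || (m == "T" && t == "G")) {
      states[i] <- "o"; 0.5
    } else {
      states[i] <- "."; 1
    }
    if (i >= 2L && i <= 13L) pen <- pen * 2
    score <- score + pen
  }
  cleavage_pos <- if (!is.na(window_start)) window_start + L - 10L else NA_integer_
  structure(list(mir_seq = paste(mir, collapse = ""),
                 transcript = transcript,
                 window = if (is.na(window_start)) NULL else
                   c(window_start, window_start + L - 1L),
                 cleavage_pos = cleavage_pos,
                 score = score,
                 alignment = paste(states, collapse = ""),
                 pass = score <= threshold),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("target site: score %.1f (%s), alignment %s\n",
              x$score, if (x$pass) "pass" else "fail", x$alignment))
  invisible(x)
}

#' Scan a transcript for complementarity sites of a miRNA
#'
#' Slides the gapless scorer over every window of a transcript and returns
#' the passing sites.
#'
#' @inheritParams score_site
#' @param transcript_seq Transcript sequence.
#' @param transcript Transcript identifier carried into the sites.
#' @return List of passing `target_site` objects.
#' @export
scan_targets <- function(mir_seq, transcript_seq, transcript = NA_character_,
                         threshold = 4) {
  mir_seq <- .normalize_seq(mir_seq)
  transcript_seq <- .normalize_seq(transcript_seq)
  mir <- strsplit(mir_seq, "")[[1L]]
  tx <- strsplit(transcript_seq, "")[[1L]]
  L <- length(mir)
  nw <- length(tx) - L + 1L
  if (nw < 1L) return(list())
  # vectorized over window starts: window offset j faces miRNA position L-j+1
  score <- numeric(nw)
  for (j in seq_len(L)) {
    i <- L - j + 1L
    mc <- mir[i]
    tj <- tx[j:(j + nw - 1L)]
    pen <- ifelse(tj == .COMPLEMENT[[mc]], 0,
                  ifelse((mc == "G" & tj == "T") | (mc == "T" & tj == "G"),
                         0.5, 1))
    if (i >= 2L && i <= 13L) pen <- pen * 2
    score <- score + pen
  }
  lapply(which(score <= threshold), function(w) {
    score_site(mir_seq, substr(transcript_seq, w, w + L - 1L),
               transcript = transcript, window_start = w,
               threshold = threshold)
  })
}

#' Validate a miRNA cleavage site against degradome libraries
#'
#' Implements the three-rule degradome test per library. Within the site's
#' target window, the candidate cleavage position is taken as the position
#' of the most abundant placed signature (ties resolved toward the canonical
#' position). Rules: (1) the mean RPM of distinct signatures whose 5' ends
#' map to the candidate position must be at least `fold` times the mean RPM
#' of the distinct signatures placed elsewhere on the transcript (an empty
#' surrounding set passes whenever the site signal is positive); (2) the most
#' abundant site signature must rank within the `top_k` most abundant
#' distinct signatures placed on the transcript, ties sharing the better
#' rank; (3) the candidate position must lie opposite miRNA nucleotide 10 or
#' 11 (AGO1 slices between guide nt 10 and 11). The site is retained when
#' all three rules hold in at least one library.
#'
#' @param site A placed [score_site()] result (needs `transcript`, `window`,
#'   `cleavage_pos`) or a list with those fields.
#' @param deg_libs List of [degradome_library()] (typically one per organ).
#' @param fold Rule-1 fold threshold (default 5, inclusive).
#' @param top_k Rule-2 rank threshold (default 12).
#' @return Object of class `cleavage_call`: `site`, `per_library`
#'   data.frame (organ, candidate position, avg_site, avg_surround, the
#'   three rule verdicts, overall) and `supported` (overall in >= 1 library).
#' @export
validate_cleavage <- function(site, deg_libs, fold = 5, top_k = 12L) {
  if (is.null(site$window) || is.na(site$transcript)) {
    stop("site must be placed on a transcript (window and transcript set)")
  }
  pos10 <- site$cleavage_pos
  pos11 <- pos10 - 1L
  rows <- lapply(deg_libs, function(deg) {
    pl <- deg$placements[deg$placements$transcript == site$transcript, , drop = FALSE]
    empty <- data.frame(organ = deg$organ, pos = NA_integer_,
                        avg_site = 0, avg_surround = 0,
                        rule1 = FALSE, rule2 = FALSE, rule3 = FALSE,
                        overall = FALSE, stringsAsFactors = FALSE)
    if (nrow(pl) == 0L) return(empty)
    in_win <- pl[pl$pos >= site$window[1L] & pl$pos <= site$window[2L], , drop = FALSE]
    if (nrow(in_win) == 0L) return(empty)
    # candidate cleavage position: most abundant signature in the window,
    # ties toward the canonical slicing position
    best <- max(in_win$count)
    cand_pos <- in_win$pos[in_win$count == best]
    p <- cand_pos[order(abs(cand_pos - pos10), cand_pos)][1L]

    sig <- unique(pl[, c("sequence", "count", "pos")])
    at_site <- sig[sig$pos == p, , drop = FALSE]
    elsewhere <- sig[sig$pos != p, , drop = FALSE]
    # distinct signatures, not positions
    site_counts <- tapply(at_site$count, at_site$sequence, max)
    elsewhere_counts <- if (nrow(elsewhere)) tapply(elsewhere$count, elsewhere$sequence, max) else numeric(0)
    avg_site <- 1e6 * mean(site_counts) / deg$total
    avg_surround <- if (length(elsewhere_counts)) 1e6 * mean(elsewhere_counts) / deg$total else 0
    rule1 <- avg_site > 0 && avg_site >= fold * avg_surround

    all_counts <- sort(tapply(sig$count, sig$sequence, max), decreasing = TRUE)
    thr <- all_counts[min(top_k, length(all_counts))]
    rule2 <- max(site_counts) >= thr

    rule3 <- p %in% c(pos10, pos11)
    data.frame(organ = deg$organ, pos = p,
               avg_site = avg_site, avg_surround = avg_surround,
               rule1 = rule1, rule2 = rule2, rule3 = rule3,
               overall = rule1 && rule2 && rule3, stringsAsFactors = FALSE)
  })
  per_library <- do.call(rbind, rows)
  rownames(per_library) <- NULL
  structure(list(site = site, per_library = per_library,
                 supported = any(per_library$overall)),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat(sprintf("cleavage call on %s at %s: supported in %d/%d libraries\n",
              x$site$transcript,
              if (is.null(x$site$cleavage_pos)) "?" else x$site$cleavage_pos,
              sum(x$per_library$overall), nrow(x$per_library)))
  invisible(x)
}

#' Classify the organ specificity of validated miRNA-target regulation
#'
#' For each cleavage call evaluated across the four organ degradome
#' libraries: a pair is organ-specific when the overall verdict holds in
#' exactly one organ, and vegetative-specific when it holds in at least one
#' of the non-floral organs and not in the flower. Pairs supported in all
#' organs are constitutive.
#'
#' @param calls List of [validate_cleavage()] results.
#' @param vegetative Organ labels counted as vegetative (default root, stem,
#'   leaf); all remaining organs are treated as reproductive.
#' @return `data.frame(transcript, cleavage_pos, organs_supported,
#'   specific_organ, organ_specific, vegetative_specific, constitutive)`.
#' @export
organ_specificity_of_regulation <- function(calls,
                                            vegetative = c("root", "stem", "leaf")) {
  rows <- lapply(calls, function(cl) {
    pl <- cl$per_library
    supp <- pl$organ[pl$overall]
    reproductive <- setdiff(pl$organ, vegetative)
    data.frame(
      mir = if (is.null(cl$site$mir_seq)) NA_character_ else cl$site$mir_seq,
      transcript = cl$site$transcript,
      cleavage_pos = cl$site$cleavage_pos,
      organs_supported = paste(supp, collapse = ","),
      specific_organ = if (length(supp) == 1L) supp else NA_character_,
      organ_specific = length(supp) == 1L,
      vegetative_specific = any(supp %in% vegetative) &&
        !any(supp %in% reproductive),
      constitutive = length(supp) == nrow(pl) && nrow(pl) > 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
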