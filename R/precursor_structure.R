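#' Parse Vienna dot-bracket notation into a base-pair partner table
#'
#' Stack parsing of a pseudoknot-free structure string over `(`, `)` and `.`.
#' Other bracket alphabets (`[`, `{`) are rejected. Unbalanced input is an
#' error reporting the position of the first violation.
#'
#' @param structure Dot-bracket string.
#' @return Object of class `pairing_map`: list with `length`, `partner`
#'   (integer vector, `NA` where unpaired, `partner[partner[i]] == i`) and
#'   `bracket` (per-position character).
#' @examples
#' pm <- parse_dot_bracket("((((....))))")
#' pm$partner[1:4]
#' @export
parse_dot_bracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  chars <- strsplit(structure, "")[[1L]]
  n <- length(chars)
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid structure character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  }
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced ')' at position %d", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) {
    stop(sprintf("%d unclosed '(' at end of string (first at position %d)",
                 length(stack), stack[1L]))
  }
  structure(list(length = n, partner = partner, bracket = chars),
            class = "pairing_map")
}

#' Serialize a pairing map back to its dot-bracket string
#' @param x A `pairing_map`.
#' @param ... Ignored.
#' @export
as.character.pairing_map <- function(x, ...) paste(x$bracket, collapse = "")

#' @export
print.pairing_map <- function(x, ...) {
  cat(sprintf("pairing map: %d nt, %d base pairs\n",
              x$length, sum(!is.na(x$partner)) / 2L))
  invisible(x)
}

.check_locus <- function(pm, start, end) {
  if (start < 1L || end > pm$length || start > end) {
    stop(sprintf("locus [%d, %d] out of structure range [1, %d]",
                 start, end, pm$length))
  }
}

#' Bracket-coverage screen of a candidate miRNA locus
#'
#' A locus passes when at least `min_frac` of its positions are paired in the
#' structure and all its paired positions carry brackets of the same
#' direction (all `(` or all `)`), i.e. the locus sits on one side of a helix
#' rather than folding onto itself.
#'
#' @param pm A [parse_dot_bracket()] pairing map.
#' @param start,end 1-based inclusive locus coordinates.
#' @param min_frac Minimum paired fraction (default 0.5, inclusive).
#' @return List: `pass`, `coverage` (paired fraction), `direction` (`"("`,
#'   `")"`, `"mixed"` or `NA` when nothing is paired).
#' @export
bracket_coverage_screen <- function(pm, start, end, min_frac = 0.5) {
  .check_locus(pm, start, end)
  idx <- start:end
  paired <- !is.na(pm$partner[idx])
  coverage <- mean(paired)
  dirs <- unique(pm$bracket[idx][paired])
  direction <- if (length(dirs) == 0L) NA_character_
               else if (length(dirs) == 1L) dirs else "mixed"
  pass <- coverage >= min_frac && length(dirs) == 1L
  list(pass = pass, coverage = coverage, direction = direction)
}

#' Locate the stem-loop (hairpin) substructure hosting a locus
#'
#' Finds the innermost hairpin enclosing the locus's base pairs: starting
#' from the pair bridging the locus to its partner region, walks inward to
#' the closing pair of the hairpin loop (rejecting branched/multiloop
#' regions), then extends the helix outward across interior loops and bulges
#' of at most `max_gap` unpaired nucleotides per step. Returns `NULL` when
#' the locus straddles the loop, its partners are split across both sides,
#' the region branches, or the helix carries fewer than `min_stem_pairs`
#' base pairs.
#'
#' @inheritParams bracket_coverage_screen
#' @param min_stem_pairs Minimum base pairs in the helix (default 15).
#' @param max_gap Maximum combined interior-loop/bulge size tolerated per
#'   helix extension step, in nucleotides (default 12).
#' @return Object of class `stem_loop`: list with `arm5`, `arm3` and `loop`
#'   intervals (`c(start, end)`), `n_pairs`, `side` the locus sits on
#'   (`"5p"`/`"3p"`) and `contains_mir` (locus fully inside one arm), or
#'   `NULL`.
#' @export
detect_stem_loop <- function(pm, start, end, min_stem_pairs = 15L,
                             max_gap = 12L) {
  .check_locus(pm, start, end)
  partner <- pm$partner
  idx <- start:end
  pos <- idx[!is.na(partner[idx])]
  if (length(pos) == 0L) return(NULL)
  part <- partner[pos]
  if (all(part > end)) {
    side <- "5p"
    i <- max(pos); j <- partner[i]
  } else if (all(part < start)) {
    side <- "3p"
    i <- max(part); j <- partner[i]
  } else {
    return(NULL) # locus straddles the loop or pairs within itself
  }

  # walk inward from (i, j) to the closing pair of the hairpin loop
  repeat {
    inside <- if (i + 1L <= j - 1L) (i + 1L):(j - 1L) else integer(0)
    inside_paired <- inside[!is.na(partner[inside])]
    if (length(inside_paired) == 0L) break
    k <- min(inside_paired)
    pk <- partner[k]
    if (pk < k) return(NULL) # malformed nesting relative to walk
    beyond <- inside_paired[inside_paired > pk]
    if (length(beyond)) return(NULL) # multiloop: more than one inner helix
    i <- k; j <- pk
  }
  loop <- c(i + 1L, j - 1L)

  # extend the helix outward from the closing pair
  a <- i; b <- j
  n_pairs <- 1L
  repeat {
    if (a <= 1L) break
    found <- NA_integer_
    lo <- max(1L, a - 1L - max_gap)
    for (x in seq(a - 1L, lo, by = -1L)) {
      if (!is.na(partner[x])) { found <- x; break }
    }
    if (is.na(found) || partner[found] <= b) break # end of helix or branch
    gap <- (a - found - 1L) + (partner[found] - b - 1L)
    if (gap > max_gap) break
    a <- found; b <- partner[found]
    n_pairs <- n_pairs + 1L
  }
  if (n_pairs < min_stem_pairs) return(NULL)

  arm5 <- c(a, i)
  arm3 <- c(j, b)
  contains_mir <- (start >= arm5[1L] && end <= arm5[2L]) ||
                  (start >= arm3[1L] && end <= arm3[2L])
  structure(list(arm5 = arm5, arm3 = arm3, loop = loop,
                 n_pairs = n_pairs, side = side,
                 contains_mir = contains_mir),
            class = "stem_loop")
}

#' @export
print.stem_loop <- function(x, ...) {
  cat(sprintf("stem-loop: 5' arm [%d, %d], loop [%d, %d], 3' arm [%d, %d], %d bp, locus %s arm, in-stem: %s\n",
              x$arm5[1], x$arm5[2], x$loop[1], x$loop[2], x$arm3[1], x$arm3[2],
              x$n_pairs, x$side, x$contains_mir))
  invisible(x)
}

#' Measure the 3' overhangs of a candidate miRNA/miRNA* duplex
#'
#' For a duplex of loci `mir = [s, e]` and `star = [s*, e*]` on one
#' structure, the miRNA-side 3' overhang is `e - partner(s*)` (how far the
#' miRNA 3' end extends past the base paired with the star 5' end) and the
#' star-side 3' overhang is `e* - partner(s)`. Dicer-like 1 processing leaves
#' exactly 2 nt on both ends. `NA` is returned for an end whose defining
#' position is unpaired or pairs outside the partner locus.
#'
#' @param pm A pairing map.
#' @param mir,star Integer vectors `c(start, end)`.
#' @return Named numeric vector `c(mir3 = ..., star3 = ...)`.
#' @export
duplex_overhangs <- function(pm, mir, star) {
  .check_locus(pm, mir[1L], mir[2L])
  .check_locus(pm, star[1L], star[2L])
  partner <- pm$partner
  p_star5 <- partner[star[1L]]
  mir3 <- if (!is.na(p_star5) && p_star5 >= mir[1L] && p_star5 <= mir[2L]) {
    mir[2L] - p_star5
  } else NA_real_
  p_mir5 <- partner[mir[1L]]
  star3 <- if (!is.na(p_mir5) && p_mir5 >= star[1L] && p_mir5 <= star[2L]) {
    star[2L] - p_mir5
  } else NA_real_
  c(mir3 = mir3, star3 = star3)
}

#' Call the miRNA* partner locus of a mature miRNA by duplex geometry
#'
#' Given a mature locus `[s, e]` on a stem arm, the star locus implied by
#' 2-nt 3' overhangs at both duplex ends is `[partner(e - 2), partner(s) + 2]`.
#' The call is rejected (`NULL`) when `s` or `e - 2` is unpaired (bulged
#' duplex boundary), the star interval leaves the transcript or overlaps the
#' mature locus, or the recomputed overhangs are not exactly (2, 2). When
#' libraries are supplied, the star sequence is looked up exactly and its
#' detection status and per-library RPM are reported; geometry without
#' detection still yields a call (`star_detected = FALSE`), as precursors may
#' have unconfirmed star strands.
#'
#' @param pm A pairing map of the precursor transcript.
#' @param start,end Mature miRNA locus on the transcript (1-based inclusive).
#' @param transcript_seq Transcript sequence (DNA space); needed for the star
#'   sequence and library lookup.
#' @param libs Optional list of [srna_library()] for star detection.
#' @return Object of class `duplex_call`: list with `mir`, `star`,
#'   `overhangs` (named `c(mir3, star3)`), `star_seq`, `star_detected`,
#'   `star_rpm` (named per-library vector); or `NULL`.
#' @export
find_star <- function(pm, start, end, transcript_seq = NULL, libs = NULL) {
  .check_locus(pm, start, end)
  partner <- pm$partner
  s <- start; e <- end
  if (e - s < 3L) stop("mature locus too short for duplex geometry")
  if (is.na(partner[s]) || is.na(partner[e - 2L])) return(NULL)
  star <- c(partner[e - 2L], partner[s] + 2L)
  if (star[1L] > star[2L]) return(NULL)
  if (star[1L] < 1L || star[2L] > pm$length) return(NULL)
  if (star[1L] <= e && star[2L] >= s) return(NULL) # overlap with mature locus
  oh <- duplex_overhangs(pm, c(s, e), star)
  if (any(is.na(oh)) || any(oh != 2)) return(NULL)

  star_seq <- NA_character_
  star_detected <- NA
  star_rpm <- NULL
  if (!is.null(transcript_seq)) {
    star_seq <- substr(.normalize_seq(transcript_seq), star[1L], star[2L])
    if (!is.null(libs)) {
      star_rpm <- vapply(libs, function(l) unname(normalize_rpm(l, star_seq)), 0)
      names(star_rpm) <- vapply(libs, .lib_key, "")
      raw <- vapply(libs, function(l) {
        cnt <- l$counts[star_seq]; if (is.na(cnt)) 0 else cnt
      }, 0)
      star_detected <- any(raw >= 1)
    }
  }
  structure(list(mir = c(s, e), star = star, overhangs = oh,
                 star_seq = star_seq, star_detected = star_detected,
                 star_rpm = star_rpm),
            class = "duplex_call")
}

#' @export
print.duplex_call <- function(x, ...) {
  cat(sprintf("duplex: mature [%d, %d] / star [%d, %d], 3' overhangs (%g, %g), star detected: %s\n",
              x$mir[1], x$mir[2], x$star[1], x$star[2],
              x$overhangs[1], x$overhangs[2], x$star_detected))
  invisible(x)
}

#' Read Vienna-style structure records
#'
#' Two- or three-line records: a `>`-header, the sequence, and the
#' dot-bracket line (an appended free-energy field in parentheses after
#' whitespace is stripped).
#'
#' @param path File of Vienna records.
#' @return Named list per transcript: `list(sequence, structure)`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no Vienna records in ", path)
  out <- vector("list", length(hdr))
  names(out) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  bounds <- c(hdr[-1L] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[(hdr[k] + 1L):bounds[k]]
    if (length(body) < 2L) stop("record ", names(out)[k], ": need sequence and structure lines")
    db <- sub("\\s+\\(.*\\)\\s*$", "", body[2L])
    out[[k]] <- list(sequence = .normalize_seq(body[1L]), structure = db)
  }
  out
}

#' Write Vienna-style structure records
#' @param records Named list of `list(sequence, structure)`.
#' @param path Output file.
#' @param rna Write sequences in RNA space (U)? Default `TRUE`.
#' @export
write_vienna <- function(records, path, rna = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(records)) {
    seq <- records[[id]]$sequence
    if (rna) seq <- chartr("T", "U", seq)
    writeLines(c(paste0(">", id), seq, records[[id]]$structure), con)
  }
  invisible(path)
}
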