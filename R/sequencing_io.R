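#' @importFrom stats rlnorm rnorm setNames t.test
#' @importFrom utils read.table write.table
NULL

.normalize_seq <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  x <- if (alphabet == "DNA") chartr("U", "T", x) else chartr("T", "U", x)
  bad <- grepl(if (alphabet == "DNA") "[^ACGTN]" else "[^ACGUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/T/U/N (first offender: ",
         x[which(bad)[1L]], ")")
  }
  x
}

#' Build a transcript catalog
#'
#' A transcript catalog is the universe of assembled transcripts all short
#' reads are placed on: a named character vector of nucleotide sequences.
#' Sequences are stored in DNA space (U converted to T); the structure module
#' converts back to U for display.
#'
#' @param sequences Named character vector (names = transcript identifiers).
#' @return Object of class `transcript_catalog`.
#' @examples
#' transcript_catalog(c(t1 = "ACGTACGT"))
#' @export
transcript_catalog <- function(sequences) {
  sequences <- unlist(sequences)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every transcript needs an identifier")
  if (anyDuplicated(ids)) stop("transcript identifiers must be unique")
  if (any(!nzchar(sequences))) stop("transcript sequences must be non-empty")
  sequences <- .normalize_seq(as.character(sequences))
  names(sequences) <- ids
  structure(sequences, class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript catalog: %d transcripts, lengths %d-%d nt\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file of transcript sequences.
#' @return A [transcript_catalog()].
#' @export
read_transcripts <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  transcript_catalog(seqs)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector or `transcript_catalog`.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(unclass(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a small-RNA library
#'
#' One sequencing replicate's collapsed small-RNA counts. `total` defaults to
#' the sum of counts but may be given explicitly when the count table is a
#' subset of a larger library (normalization then still uses the full library
#' size).
#'
#' @param counts Named numeric vector: sequence -> raw read count.
#' @param organ,replicate Labels for the library.
#' @param total Library size used for RPM; default `sum(counts)`.
#' @return Object of class `srna_library`.
#' @export
srna_library <- function(counts, organ, replicate, total = NULL) {
  seqs <- names(counts)
  if (is.null(seqs)) stop("'counts' must be named by sequence")
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("raw counts must be non-negative integers")
  }
  seqs <- .normalize_seq(seqs)
  if (anyDuplicated(seqs)) {
    counts <- tapply(counts, seqs, sum)
    seqs <- names(counts)
    counts <- as.numeric(counts)
  }
  keep <- counts > 0
  counts <- counts[keep]; seqs <- seqs[keep]
  if (is.null(total)) total <- sum(counts)
  if (length(counts) == 0L || total <= 0) stop("empty library")
  if (total < sum(counts)) stop("'total' smaller than the sum of counts")
  structure(list(organ = as.character(organ),
                 replicate = as.character(replicate),
                 counts = setNames(counts, seqs),
                 total = total),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("sRNA library %s_%s: %d distinct sequences, %s reads\n",
              x$organ, x$replicate, length(x$counts),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Read a collapsed small-RNA library
#'
#' Accepts the two field formats in common use: a collapsed FASTA whose
#' headers carry the read count as the last delimiter-separated token
#' (`>id_123`), or a two-column TSV of `sequence<TAB>count`. Duplicate
#' sequences are aggregated. Malformed records are reported with their
#' line numbers.
#'
#' @param path Input file.
#' @param organ,replicate Labels for the library.
#' @param delim Header delimiter(s) tried for collapsed FASTA; default `_`
#'   then `-`.
#' @param total Optional full library size (see [srna_library()]).
#' @return An `srna_library`.
#' @export
read_collapsed_srna <- function(path, organ, replicate, delim = c("_", "-"),
                                total = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty library: ", path)
  if (startsWith(lines[[1L]], ">")) {
    hdr_idx <- which(startsWith(lines, ">"))
    if (length(hdr_idx) == 0L) stop("no FASTA records in ", path)
    seqs <- character(length(hdr_idx))
    cnts <- numeric(length(hdr_idx))
    bounds <- c(hdr_idx[-1L] - 1L, length(lines))
    for (k in seq_along(hdr_idx)) {
      hdr <- sub("^>", "", trimws(lines[hdr_idx[k]]))
      toks <- unlist(strsplit(hdr, paste0("[", paste(delim, collapse = ""), "]")))
      cnt <- suppressWarnings(as.numeric(toks[length(toks)]))
      if (is.na(cnt) || cnt != floor(cnt)) {
        stop(sprintf("record %d (line %d): header '%s' does not end in an integer count",
                     k, hdr_idx[k], hdr))
      }
      body <- lines[(hdr_idx[k] + 1L):bounds[k]]
      if (hdr_idx[k] + 1L > bounds[k] || !all(nzchar(body))) {
        stop(sprintf("record %d (line %d): missing sequence", k, hdr_idx[k]))
      }
      seqs[k] <- paste(trimws(body), collapse = "")
      cnts[k] <- cnt
    }
  } else {
    fields <- strsplit(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      stop(sprintf("line %d: expected 'sequence<TAB>count'", which(nf < 2L)[1L]))
    }
    seqs <- vapply(fields, `[[`, "", 1L)
    cnt_txt <- vapply(fields, `[[`, "", 2L)
    cnts <- suppressWarnings(as.numeric(cnt_txt))
    bad <- is.na(cnts) | cnts != floor(cnts)
    if (any(bad)) {
      stop(sprintf("line %d: count '%s' is not an integer",
                   which(bad)[1L], cnt_txt[which(bad)[1L]]))
    }
  }
  srna_library(setNames(cnts, seqs), organ, replicate, total = total)
}

#' Reads-per-million accumulation of sequences in a library
#'
#' RPM of a sequence is `1e6 * raw count / library total`. Sequences absent
#' from the library have RPM 0.
#'
#' @param lib An `srna_library` (or `degradome_library`, which shares the
#'   `counts`/`total` contract via its `tags`).
#' @param seqs Character vector of query sequences, or `NULL` for the full
#'   named RPM vector of the library.
#' @return Numeric RPM value(s).
#' @examples
#' lib <- srna_library(c(ACGTACGTACGTACGTACGTA = 50), "root", "1", total = 2e6)
#' normalize_rpm(lib, "ACGTACGTACGTACGTACGTA")
#' @export
normalize_rpm <- function(lib, seqs = NULL) {
  counts <- if (inherits(lib, "degradome_library")) lib$tags else lib$counts
  total <- lib$total
  if (is.null(total) || total <= 0) stop("library total must be positive")
  if (is.null(seqs)) return(1e6 * counts / total)
  seqs <- .normalize_seq(as.character(seqs))
  out <- counts[seqs]
  out[is.na(out)] <- 0
  1e6 * setNames(as.numeric(out), seqs) / total
}

#' Convert a raw mapped-read count matrix to RPKM
#'
#' RPKM of a cell = reads mapped to the transcript /
#' (total reads mapped in that sample, in millions, x transcript length in
#' kilobases). Column totals are taken over all rows of the matrix, so the
#' matrix must contain every transcript reads were counted on.
#'
#' @param raw Numeric matrix, rows = transcripts (rownames required),
#'   columns = samples.
#' @param lengths Named numeric vector of transcript lengths in nucleotides;
#'   every row of `raw` must be present.
#' @return Matrix of RPKM values with attribute `unit = "rpkm"`.
#' @examples
#' m <- matrix(100, 1, 1, dimnames = list("t1", "root_1"))
#' compute_rpkm(rbind(m, t2 = 9999900), c(t1 = 1000, t2 = 500))["t1", ]
#' @export
compute_rpkm <- function(raw, lengths) {
  if (!is.matrix(raw) || is.null(rownames(raw)) || is.null(colnames(raw))) {
    stop("'raw' must be a matrix with transcript rownames and sample colnames")
  }
  if (anyDuplicated(colnames(raw))) stop("sample (column) ids must be unique")
  if (any(raw < 0)) stop("raw counts must be non-negative")
  missing_len <- setdiff(rownames(raw), names(lengths))
  if (length(missing_len)) {
    stop("no length for transcript(s): ", paste(utils::head(missing_len, 3), collapse = ", "))
  }
  len_kb <- lengths[rownames(raw)] / 1e3
  col_tot <- colSums(raw)
  if (any(col_tot == 0)) {
    stop("zero mapped-read total in sample(s): ",
         paste(colnames(raw)[col_tot == 0], collapse = ", "))
  }
  rpkm <- sweep(raw, 2L, col_tot / 1e6, "/")
  rpkm <- sweep(rpkm, 1L, len_kb, "/")
  attr(rpkm, "unit") <- "rpkm"
  rpkm
}

#' Place a short read on a transcript catalog by perfect sense match
#'
#' Reports every exact sense-strand occurrence of `query` on every transcript,
#' with 1-based inclusive coordinates. T and U are unified before comparison.
#' Antisense placements are off by default (a precursor transcript carries its
#' small RNAs in sense).
#'
#' @param query Single sequence (pipeline reads are 15 nt or longer; shorter
#'   queries are accepted but will multi-map heavily).
#' @param catalog A [transcript_catalog()] (or named character vector).
#' @param antisense Also report reverse-complement matches (flagged in the
#'   `strand` column)? Default `FALSE`.
#' @return `data.frame(transcript, start, end, strand)`, sorted by transcript
#'   then start; zero rows when the query is absent.
#' @export
map_perfect <- function(query, catalog, antisense = FALSE) {
  query <- .normalize_seq(query)
  if (length(query) != 1L || nchar(query) < 1L) {
    stop("'query' must be a single non-empty sequence")
  }
  subject <- Biostrings::DNAStringSet(unclass(catalog))
  hits <- function(q, strand) {
    m <- Biostrings::vmatchPattern(q, subject)
    st <- Biostrings::startIndex(m)
    n <- lengths(st)
    keep <- n > 0L
    if (!any(keep)) {
      return(data.frame(transcript = character(), start = integer(),
                        end = integer(), strand = character()))
    }
    data.frame(
      transcript = rep(names(subject)[keep], n[keep]),
      start = unlist(st[keep]),
      end = unlist(st[keep]) + nchar(q) - 1L,
      strand = strand,
      stringsAsFactors = FALSE
    )
  }
  out <- hits(query, "+")
  if (antisense) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
    out <- rbind(out, hits(rc, "-"))
  }
  out <- out[order(out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a count matrix TSV (header row of sample ids, first column
#' of transcript ids)
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_count_matrix
#' @param mat Matrix to write.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(transcript = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
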