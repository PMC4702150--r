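#' Build a mature miRNA candidate catalog from a reference collection
#'
#' Matches a mature-miRNA reference set (miRBase-style, name -> sequence)
#' against a set of small-RNA libraries by exact full-length sequence
#' identity (T/U unified). Reference entries undetectable in every library
#' are discarded; entries sharing one sequence are collapsed into a single
#' candidate carrying all source names. Surviving candidates are renamed
#' `<prefix><n>` in a deterministic order: descending total raw count across
#' libraries, ties broken lexicographically by sequence.
#'
#' @param reference Named character vector, reference name -> mature sequence.
#' @param libs List of [srna_library()] covering the design.
#' @param design An [organ_design()].
#' @param prefix Identifier prefix for renaming (default `"can-miR-"`).
#' @return A data.frame of class `mirna_catalog`: columns `id`, `sequence`,
#'   `sources` (comma-separated reference names), one `count.<sample>` and
#'   `rpm.<sample>` column per library, and one `mean_rpm.<organ>` column per
#'   organ (mean of replicate RPMs).
#' @export
match_reference <- function(reference, libs, design, prefix = "can-miR-") {
  if (length(reference) == 0L) stop("empty miRNA reference")
  stopifnot(inherits(design, "organ_design"))
  libs <- .check_libs(libs, design)
  seqs <- .normalize_seq(as.character(reference))
  src <- split(names(reference), seqs)
  uniq <- names(src)

  counts <- vapply(libs, function(l) {
    out <- l$counts[uniq]
    out[is.na(out)] <- 0
    as.numeric(out)
  }, numeric(length(uniq)))
  if (length(uniq) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- vapply(libs, .lib_key, "")
  rownames(counts) <- uniq

  detected <- rowSums(counts) > 0
  if (!any(detected)) {
    warning("no reference miRNA detected in any library")
  }
  counts <- counts[detected, , drop = FALSE]
  uniq <- uniq[detected]
  src <- src[detected]

  ord <- order(-rowSums(counts), uniq)
  counts <- counts[ord, , drop = FALSE]
  uniq <- uniq[ord]
  src <- src[ord]

  totals <- vapply(libs, function(l) l$total, 0)
  rpm <- sweep(counts, 2L, totals / 1e6, "/")
  organs_of <- vapply(libs, function(l) l$organ, "")
  mean_rpm <- vapply(design$organs, function(o) {
    rowMeans(rpm[, organs_of == o, drop = FALSE])
  }, numeric(length(uniq)))
  if (length(uniq) == 1L) mean_rpm <- matrix(mean_rpm, nrow = 1L,
                                             dimnames = list(NULL, design$organs))

  out <- data.frame(
    id = paste0(prefix, seq_along(uniq)),
    sequence = uniq,
    sources = vapply(src, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  cm <- as.data.frame(counts); names(cm) <- paste0("count.", colnames(counts))
  rm_ <- as.data.frame(rpm); names(rm_) <- paste0("rpm.", colnames(rpm))
  mm <- as.data.frame(mean_rpm); names(mm) <- paste0("mean_rpm.", design$organs)
  out <- cbind(out, cm, rm_, mm)
  rownames(out) <- NULL
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' Filter a miRNA catalog by per-organ mean accumulation
#'
#' Keeps candidates whose mean RPM (averaged over an organ's replicates)
#' reaches `min_rpm` in at least one organ. Monotone in `min_rpm`.
#'
#' @param catalog A `mirna_catalog` from [match_reference()].
#' @param min_rpm Threshold in RPM (default 5, inclusive).
#' @return Filtered `mirna_catalog`.
#' @export
expression_filter <- function(catalog, min_rpm = 5) {
  stopifnot(inherits(catalog, "mirna_catalog"))
  mm <- as.matrix(catalog[, grep("^mean_rpm\\.", names(catalog)), drop = FALSE])
  keep <- apply(mm, 1L, max) >= min_rpm
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a miRBase-style mature miRNA FASTA
#'
#' First whitespace token of each header is taken as the reference name.
#'
#' @param path FASTA file.
#' @return Named character vector name -> sequence (DNA space).
#' @export
read_mature_reference <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- .normalize_seq(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}
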