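#' Transcripts highly expressed in organ A relative to organ B
#'
#' A transcript is called high in A versus B when all three criteria hold:
#' mean RPKM over A's replicates is at least `fold` times the mean over B's
#' replicates (boundary inclusive), a two-sample two-tailed Student's t-test
#' (pooled variance) gives p below `alpha`, and the A mean is at least
#' `floor` RPKM. With B mean exactly zero the fold criterion reduces to the
#' floor criterion (presence/absence is the strongest fold). When both groups
#' have zero variance, p is taken as 0 if the means differ and 1 otherwise
#' (limit behaviour of the statistic).
#'
#' @param rpkm RPKM matrix, columns named `"<organ>_<replicate>"`.
#' @param design An [organ_design()].
#' @param organ_a,organ_b Organ labels from the design.
#' @param fold Fold-change threshold (default 5, inclusive).
#' @param alpha t-test significance threshold (default 0.05, exclusive).
#' @param floor Minimum A mean in RPKM (default 1, inclusive).
#' @param details Return the full per-transcript table instead of the id set?
#' @return Character vector of transcript ids (or, with `details = TRUE`, a
#'   data.frame with means, fold ratio, p-value and verdict per transcript).
#' @export
pairwise_high <- function(rpkm, design, organ_a, organ_b,
                          fold = 5, alpha = 0.05, floor = 1,
                          details = FALSE) {
  stopifnot(inherits(design, "organ_design"))
  organ_a <- match.arg(organ_a, design$organs)
  organ_b <- match.arg(organ_b, design$organs)
  cols_a <- sample_ids(design, organ_a)
  cols_b <- sample_ids(design, organ_b)
  missing <- setdiff(c(cols_a, cols_b), colnames(rpkm))
  if (length(missing)) stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stop("need at least two replicates per organ for the t-test")
  }
  a <- rpkm[, cols_a, drop = FALSE]
  b <- rpkm[, cols_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  fold_ok <- ifelse(mean_b > 0, mean_a >= fold * mean_b, mean_a >= floor)
  floor_ok <- mean_a >= floor
  pvals <- rep(NA_real_, nrow(rpkm))
  cand <- which(fold_ok & floor_ok)
  for (i in cand) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      pvals[i] <- if (mean_a[i] == mean_b[i]) 1 else 0
    } else {
      pvals[i] <- t.test(xa, xb, var.equal = TRUE)$p.value
    }
  }
  verdict <- fold_ok & floor_ok & !is.na(pvals) & pvals < alpha
  if (details) {
    data.frame(transcript = rownames(rpkm),
               mean_a = mean_a, mean_b = mean_b,
               fold_ratio = ifelse(mean_b > 0, mean_a / mean_b, Inf),
               p_value = pvals,
               fold_ok = fold_ok, floor_ok = floor_ok,
               verdict = verdict, row.names = NULL)
  } else {
    rownames(rpkm)[verdict]
  }
}

#' Transcripts highly expressed in exactly one organ
#'
#' Organ O's set is the intersection of [pairwise_high()] results of O against
#' every other organ of the design; by construction the per-organ sets are
#' pairwise disjoint.
#'
#' @inheritParams pairwise_high
#' @return Named list (one element per organ) of transcript id vectors.
#' @export
organ_specific_transcripts <- function(rpkm, design, fold = 5, alpha = 0.05,
                                       floor = 1) {
  stopifnot(inherits(design, "organ_design"))
  out <- lapply(design$organs, function(o) {
    others <- setdiff(design$organs, o)
    sets <- lapply(others, function(x) {
      pairwise_high(rpkm, design, o, x, fold = fold, alpha = alpha, floor = floor)
    })
    Reduce(intersect, sets)
  })
  names(out) <- design$organs
  out
}

.lib_key <- function(lib) paste(lib$organ, lib$replicate, sep = "_")

.check_libs <- function(libs, design) {
  keys <- vapply(libs, .lib_key, "")
  want <- sample_ids(design)
  missing <- setdiff(want, keys)
  if (length(missing)) {
    stop("missing libraries for samples: ", paste(missing, collapse = ", "))
  }
  libs[match(want, keys)]
}

#' Small RNAs specifically accumulated in exactly one organ
#'
#' A sequence is called specific to organ O when its RPM reaches `rpm_min` in
#' at least one replicate library of O and its raw count is zero in every
#' library of every other organ ("could not be detected" is read literally:
#' one raw read elsewhere disqualifies).
#'
#' @param libs List of [srna_library()] objects covering the full design.
#' @param design An [organ_design()].
#' @param rpm_min RPM threshold (default 10, inclusive).
#' @return Named list (per organ) of sequence vectors; sets are pairwise
#'   disjoint by construction.
#' @export
organ_specific_srnas <- function(libs, design, rpm_min = 10) {
  libs <- .check_libs(libs, design)
  organs_of <- vapply(libs, function(l) l$organ, "")
  out <- lapply(design$organs, function(o) {
    own <- libs[organs_of == o]
    other <- libs[organs_of != o]
    # candidates: reach rpm_min in >=1 replicate of o
    cand <- unique(unlist(lapply(own, function(l) {
      names(l$counts)[1e6 * l$counts / l$total >= rpm_min]
    })))
    if (length(cand) == 0L) return(character())
    detected_elsewhere <- Reduce(`|`, lapply(other, function(l) {
      cand %in% names(l$counts)
    }))
    sort(cand[!detected_elsewhere])
  })
  names(out) <- design$organs
  out
}

#' Pairwise overlap of non-redundant sequence sets between organs
#'
#' Each organ's set is the union of its replicates' distinct sequences; the
#' result is the symmetric matrix of pairwise intersection cardinalities
#' (diagonal = per-organ set size).
#'
#' @inheritParams organ_specific_srnas
#' @return Integer matrix with organ dimnames.
#' @export
library_overlap <- function(libs, design) {
  libs <- .check_libs(libs, design)
  organs_of <- vapply(libs, function(l) l$organ, "")
  sets <- lapply(design$organs, function(o) {
    unique(unlist(lapply(libs[organs_of == o], function(l) names(l$counts))))
  })
  names(sets) <- design$organs
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(design$organs, design$organs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  m
}
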