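#' Define an organ x replicate experimental design
#'
#' The pipeline works on a fixed set of organs, each sequenced with the same
#' number of biological replicates. The default mirrors the common four-organ
#' plant design (root, stem, leaf, flower) with two replicates per organ.
#'
#' @param organs Ordered character vector of organ labels (at least two).
#' @param replicates Integer number of replicates per organ (at least two,
#'   uniform across organs; two-sample t-tests are undefined below two).
#'
#' @return An object of class `organ_design`: a list with elements `organs`
#'   and `replicates`.
#' @examples
#' d <- organ_design()
#' sample_ids(d)
#' @export
organ_design <- function(organs = c("root", "stem", "leaf", "flower"),
                         replicates = 2L) {
  organs <- as.character(organs)
  replicates <- as.integer(replicates)
  if (length(organs) < 2L) stop("an organ design needs at least two organs")
  if (anyDuplicated(organs)) stop("organ labels must be unique")
  if (length(replicates) != 1L || is.na(replicates) || replicates < 2L) {
    stop("'replicates' must be a single integer >= 2")
  }
  structure(list(organs = organs, replicates = replicates),
            class = "organ_design")
}

#' @export
print.organ_design <- function(x, ...) {
  cat("organ design:", paste(x$organs, collapse = ", "),
      sprintf("(%d replicates each)\n", x$replicates))
  invisible(x)
}

#' Sample identifiers of a design
#'
#' @param design An `organ_design`.
#' @param organ Optional single organ; restrict to its samples.
#' @return Character vector `"<organ>_<replicate>"`, organs in design order.
#' @export
sample_ids <- function(design, organ = NULL) {
  stopifnot(inherits(design, "organ_design"))
  organs <- if (is.null(organ)) design$organs else match.arg(organ, design$organs)
  as.vector(vapply(organs, function(o) {
    paste(o, seq_len(design$replicates), sep = "_")
  }, character(design$replicates)))
}
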