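#' Split and merge errors of a predicted grouping
#'
#' Both arguments must partition the same universe of 2D segments (matched
#' by slice and segment index). A split error is counted whenever a true 3D
#' object is spread over several predicted objects; a merge error whenever
#' several true objects are absorbed into one predicted object. Counts use
#' the excess-pieces convention: a true object covered by m predicted
#' labels contributes m-1 split errors, and a predicted object covering t
#' true labels contributes t-1 merge errors, which makes totals additive
#' and makes the two counts exact duals under swapping the arguments.
#'
#' @param pred,truth \linkS4class{Linked3D} objects over the same segments,
#'   or plain integer label vectors of equal length.
#' @return an \linkS4class{ErrorReport}.
#' @examples
#' splitMergeErrors(c(1, 1, 2), c(1, 1, 1))  # one split, no merge
#' @export
splitMergeErrors <- function(pred, truth) {
  pl <- .labelsOf(pred); tl <- .labelsOf(truth)
  if (is(pred, "Linked3D") && is(truth, "Linked3D")) {
    a <- pred@segments[, c("slice", "seg", "area")]
    b <- truth@segments[, c("slice", "seg", "area")]
    if (nrow(a) != nrow(b) ||
        !all(a$slice == b$slice & a$seg == b$seg & a$area == b$area))
      stop("pred and truth must cover the identical set of 2D segments")
  } else if (length(pl) != length(tl)) {
    stop("pred and truth must cover the identical set of 2D segments")
  }
  ct <- table(tl, pl)
  split <- sum(rowSums(ct > 0) - 1L)
  merge <- sum(colSums(ct > 0) - 1L)
  new("ErrorReport", splitErrors = as.integer(split),
      mergeErrors = as.integer(merge),
      total = as.integer(split + merge))
}

.labelsOf <- function(x) {
  if (is(x, "Linked3D")) x@labels else as.integer(x)
}

#' Write an error report as JSON
#' @param report an \linkS4class{ErrorReport}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeErrorReport <- function(report, path) {
  jsonlite::write_json(
    list(splitErrors = report@splitErrors, mergeErrors = report@mergeErrors,
         total = report@total),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
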