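#' Build a SliceStack from a list of mask matrices
#'
#' @param masks list of 2D integer matrices (z order), or a 3D array with the
#'   third dimension indexing slices.
#' @param voxelSize numeric(3), (x, y, z) voxel edge lengths in nm.
#' @return a \linkS4class{SliceStack}.
#' @examples
#' s <- matrix(0L, 8, 8); s[3:5, 3:5] <- 1L
#' stk <- SliceStack(list(s, s, s))
#' nSlices(stk)
#' @export
SliceStack <- function(masks, voxelSize = c(2, 2, 50)) {
  if (is.array(masks) && length(dim(masks)) == 3L)
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("SliceStack", masks = masks, voxelSize = as.numeric(voxelSize))
}

#' Construct linker parameters
#'
#' Defaults follow the operating point that works well for blob-like
#' (mitochondria-like) structures: \code{Tl=0.01}, \code{Th=0.4},
#' \code{Ts=0.03}, \code{lambda=0.5}, skip connection on. The
#' \code{"synapse"} preset raises \code{lambda} to 2 so the shape term
#' dominates, suiting thin sheet-like structures whose consecutive
#' cross-sections overlap little.
#'
#' @param Tl,Th coarse screening thresholds, \code{0 <= Tl <= Th <= 1}.
#' @param Ts fine-connection threshold in \code{[0, Th)}.
#' @param lambda balance between position and shape terms, >= 0.
#' @param scaleGrid scale factors tried by the shape term.
#' @param maxShift translation jitter half-width (px) around centroid
#'   alignment.
#' @param skipEnabled bridge single missing slices?
#' @param preset \code{"mitochondria"} (default) or \code{"synapse"}.
#' @return a \linkS4class{LinkParams}.
#' @examples
#' linkParams()
#' linkParams(preset = "synapse")
#' @export
linkParams <- function(Tl = 0.01, Th = 0.4, Ts = 0.03, lambda = 0.5,
                       scaleGrid = c(0.80, 0.90, 1.00, 1/0.9, 1.25),
                       maxShift = 1L, skipEnabled = TRUE,
                       preset = c("mitochondria", "synapse")) {
  preset <- match.arg(preset)
  if (preset == "synapse" && missing(lambda)) lambda <- 2
  new("LinkParams", Tl = Tl, Th = Th, Ts = Ts, lambda = lambda,
      scaleGrid = as.numeric(scaleGrid), maxShift = as.integer(maxShift),
      skipEnabled = isTRUE(skipEnabled))
}

#' Parameters reproducing plain 3D connected-component labeling
#'
#' With \code{lambda=0}, \code{Ts=0}, \code{Tl=0}, \code{Th=1} and skip
#' connection off, the linker connects two segments exactly when their
#' masks share a pixel, so the final partition equals 3D connected-component
#' labeling with overlap (face) connectivity across slices — the
#' \code{bwconncomp}-style baseline. \code{Th=1} ensures every candidate
#' pair is validated by the position term rather than accepted on bounding
#' boxes alone.
#'
#' @return a \linkS4class{LinkParams}.
#' @seealso [cc3dOverlap()]
#' @export
bwconncompParams <- function() {
  new("LinkParams", Tl = 0, Th = 1, Ts = 0, lambda = 0,
      scaleGrid = 1, maxShift = 0L, skipEnabled = FALSE)
}

#' @describeIn SliceStack number of slices
#' @param x,object a SliceStack.
#' @export
nSlices <- function(x) length(x@masks)

#' @describeIn SliceStack slice dimensions (rows, cols)
#' @export
sliceDim <- function(x) dim(x@masks[[1L]])

#' @describeIn SliceStack voxel size accessor
#' @export
voxelSize <- function(x) x@voxelSize

#' Final 3D label of every 2D segment
#' @param x a \linkS4class{Linked3D}.
#' @return integer vector, parallel to \code{segmentTable(x)}.
#' @export
segmentLabels <- function(x) x@labels

#' Per-segment table of a Linked3D
#' @param x a \linkS4class{Linked3D}.
#' @return data.frame with slice, seg, area, bbox and centroid columns.
#' @export
segmentTable <- function(x) x@segments

#' Number of distinct 3D objects in a grouping
#' @param x a \linkS4class{Linked3D}.
#' @export
nObjects <- function(x) length(unique(x@labels))

#' @describeIn ErrorReport split error count
#' @param x an ErrorReport.
#' @export
splitErrors <- function(x) x@splitErrors

#' @describeIn ErrorReport merge error count
#' @export
mergeErrors <- function(x) x@mergeErrors

#' @describeIn ErrorReport total error count
#' @export
totalErrors <- function(x) x@total

setMethod("show", "SliceStack", function(object) {
  d <- dim(object@masks[[1L]])
  cat(sprintf("SliceStack: %d slice(s) of %d x %d, voxel %g x %g x %g nm\n",
              length(object@masks), d[1], d[2],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "LinkParams", function(object) {
  cat(sprintf(
    "LinkParams: Tl=%g Th=%g Ts=%g lambda=%g | scales {%s} shift +/-%d px | skip %s\n",
    object@Tl, object@Th, object@Ts, object@lambda,
    paste(signif(object@scaleGrid, 3), collapse = ", "),
    object@maxShift, if (object@skipEnabled) "on" else "off"))
})

setMethod("show", "Linked3D", function(object) {
  cat(sprintf("Linked3D: %d segment(s) over %d slice(s) -> %d object(s)\n",
              nrow(object@segments), object@nSlices,
              length(unique(object@labels))))
  if (nrow(object@skipPairs) > 0L)
    cat(sprintf("  %d skip connection(s) accepted\n", nrow(object@skipPairs)))
})

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf("ErrorReport: split=%d merge=%d total=%d\n",
              object@splitErrors, object@mergeErrors, object@total))
})
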