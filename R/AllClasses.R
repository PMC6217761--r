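#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums
NULL

#' SliceStack: an ordered stack of 2D segmentation masks
#'
#' Container for serial-section segmentation masks. Each slice is an integer
#' matrix of identical dimensions; 0 is background. Masks may be binary
#' (foreground split into connected components downstream) or pre-labeled
#' (each distinct nonzero value on a slice is one segment). The voxel size
#' records the anisotropic resolution, e.g. \code{c(2, 2, 50)} nm for
#' ATUM-SEM data with fine in-plane and coarse axial sampling.
#'
#' @slot masks list of integer matrices (slices, in z order).
#' @slot voxelSize numeric(3): (x, y, z) edge lengths in nanometres.
#' @exportClass SliceStack
setClass("SliceStack",
  representation(masks = "list", voxelSize = "numeric"),
  validity = function(object) {
    m <- object@masks
    if (length(m) < 1L) return("a SliceStack needs at least one slice")
    if (!all(vapply(m, is.matrix, logical(1))))
      return("all slices must be matrices")
    d <- vapply(m, dim, integer(2))
    if (length(m) > 1L && (length(unique(d[1, ])) != 1L ||
                           length(unique(d[2, ])) != 1L))
      return("all slices must share identical dimensions")
    if (any(vapply(m, function(s) any(s < 0), logical(1))))
      return("mask values must be non-negative integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive reals (x, y, z) in nm")
    TRUE
  })

#' LinkParams: thresholds and transformation set for the linker
#'
#' Parameters of the coarse-to-fine connection.
#' Coarse screening uses two bounding-box IoU thresholds
#' \code{0 <= Tl <= Th <= 1}: pairs at or above \code{Th} connect outright,
#' pairs below \code{Tl} are discarded, pairs in between are validated with
#' the refined similarity \eqn{(P^2 + \lambda S^2)/(1+\lambda)} and connected
#' when it exceeds \code{Ts} (strictly). \code{lambda} balances the position
#' term P (in-place mask IoU) against the shape term S (best mask IoU over a
#' scaling+translation search); blob-like structures such as mitochondria
#' overlap strongly slice to slice and want small \code{lambda}, thin
#' sheet-like structures such as synaptic clefts drift and want larger
#' \code{lambda}. The transformation set is a scale grid applied about the
#' source centroid, crossed with centroid-aligning translations jittered by
#' up to \code{maxShift} px; the identity transformation is always included.
#'
#' @slot Tl lower coarse threshold in [0,1].
#' @slot Th upper coarse threshold, \code{Tl <= Th <= 1}.
#' @slot Ts fine-connection threshold in [0, Th).
#' @slot lambda shape/position balance, >= 0.
#' @slot scaleGrid numeric vector of scale factors (the data-driven
#'   equivalent-diameter ratio of each pair is appended at evaluation time).
#' @slot maxShift integer, half-width of the translation jitter in px.
#' @slot skipEnabled logical, whether to bridge single missing slices.
#' @exportClass LinkParams
setClass("LinkParams",
  representation(Tl = "numeric", Th = "numeric", Ts = "numeric",
                 lambda = "numeric", scaleGrid = "numeric",
                 maxShift = "integer", skipEnabled = "logical"),
  validity = function(object) {
    if (!(object@Tl >= 0 && object@Tl <= object@Th && object@Th <= 1))
      return("need 0 <= Tl <= Th <= 1")
    if (!(object@Ts >= 0 && object@Ts < object@Th))
      return("need Ts in [0, Th)")
    if (object@lambda < 0) return("lambda must be >= 0")
    if (any(object@scaleGrid <= 0)) return("scale factors must be positive")
    if (object@maxShift < 0L) return("maxShift must be >= 0")
    TRUE
  })

#' Linked3D: a 3D grouping of 2D segments
#'
#' The result of the linker, the 3D connected-component baseline, or the
#' synthetic generator's ground truth: a partition of all 2D segments of a
#' stack into 3D objects. Segments are enumerated per slice in row-major
#' scan order of their first foreground pixel; \code{labels} carries one
#' final 3D label per segment (the minimum seed label of its group).
#'
#' @slot segments data.frame with one row per 2D segment: \code{slice},
#'   \code{seg} (index within slice), \code{area}, tight half-open bounding
#'   box \code{y0,x0,y1,x1}, centroid \code{cy,cx}.
#' @slot pixels list of integer vectors: linear pixel indices (column-major
#'   within the slice) of each segment.
#' @slot labels integer vector of final 3D labels, parallel to segments.
#' @slot dim integer(2): slice height and width.
#' @slot nSlices integer: number of slices in the originating stack.
#' @slot fineMatrices list of binary adjacent-slice connection matrices
#'   (dgCMatrix), empty unless produced by the linker.
#' @slot skipPairs data.frame of accepted skip connections (columns
#'   \code{from}, \code{to}: global segment ids), possibly empty.
#' @slot categories list (per slice) of logical k_i x 7 matrices with
#'   columns O, S, E, S1, M1, S2, M2, empty unless produced by the linker.
#' @exportClass Linked3D
setClass("Linked3D",
  representation(segments = "data.frame", pixels = "list",
                 labels = "integer", dim = "integer", nSlices = "integer",
                 fineMatrices = "list", skipPairs = "data.frame",
                 categories = "list"),
  validity = function(object) {
    n <- nrow(object@segments)
    if (length(object@labels) != n)
      return("labels must have one entry per segment")
    if (length(object@pixels) != n)
      return("pixels must have one entry per segment")
    if (n > 0L && any(is.na(object@labels)))
      return("every segment must carry a final label")
    TRUE
  })

#' ErrorReport: split and merge error counts
#'
#' Split errors count excess predicted pieces of true objects (a k-way split
#' of one true object counts k-1); merge errors count excess true objects
#' absorbed into predicted objects. \code{total = split + merge}.
#'
#' @slot splitErrors integer >= 0.
#' @slot mergeErrors integer >= 0.
#' @slot total integer, sum of the two.
#' @exportClass ErrorReport
setClass("ErrorReport",
  representation(splitErrors = "integer", mergeErrors = "integer",
                 total = "integer"),
  validity = function(object) {
    if (object@splitErrors < 0L || object@mergeErrors < 0L)
      return("error counts must be non-negative")
    if (object@total != object@splitErrors + object@mergeErrors)
      return("total must equal splitErrors + mergeErrors")
    TRUE
  })
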