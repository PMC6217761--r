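## Coarse/refined pairwise similarity between 2D segments on two slices.

#' Three-way coarse screening decision
#'
#' Classifies a bounding-box IoU value against the coarse thresholds:
#' values in \code{[Th, 1]} connect outright (\code{"CONNECT"}), values in
#' \code{[0, Tl)} are discarded (\code{"NONE"}), values in \code{[Tl, Th)}
#' are handed to the mask-level validation (\code{"VALIDATE"}).
#'
#' @param c coarse similarity in [0, 1].
#' @param params a \linkS4class{LinkParams}.
#' @return one of \code{"CONNECT"}, \code{"NONE"}, \code{"VALIDATE"}.
#' @examples
#' p <- linkParams()
#' classifyCoarse(0.5, p)    # CONNECT
#' classifyCoarse(0.005, p)  # NONE
#' classifyCoarse(0.2, p)    # VALIDATE
#' @export
classifyCoarse <- function(c, params) {
  if (is.na(c) || c < 0 || c > 1)
    stop("coarse similarity must lie in [0, 1]")
  if (c >= params@Th) "CONNECT"
  else if (c < params@Tl) "NONE"
  else "VALIDATE"
}

## round half away from zero; fixed rule so rasterization is deterministic
.rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)

## pixel-set IoU of two linear-index sets (same slice geometry)
.pixelIoU <- function(a, b) {
  ni <- sum(a %in% b)
  nu <- length(a) + length(b) - ni
  if (nu == 0L) return(0)
  ni / nu
}

#' Position term: in-place mask IoU of two segments
#'
#' The two segments are rasterized on the minimal common domain spanning
#' both bounding boxes and compared pixel for pixel; the IoU is independent
#' of the crop as long as it contains both masks, so it is computed directly
#' on absolute pixel coordinates. Measures how much of the structure stays
#' put from one slice to the next.
#'
#' @param segA,segB segments as returned by [extractSegments()] (from any
#'   two slices of the same stack geometry).
#' @return IoU in [0, 1].
#' @export
positionTerm <- function(segA, segB) {
  .pixelIoU(segA$pixels, segB$pixels)
}

## enumerate transformed copies of segA's pixel coordinate set and score
## each against segB; used by shapeTerm and by nothing else
.shapeCandidates <- function(segA, segB, params, H) {
  yA <- ((segA$pixels - 1L) %% H) + 1L
  xA <- ((segA$pixels - 1L) %/% H) + 1L
  cA <- segA$centroid; cB <- segB$centroid
  scales <- unique(c(params@scaleGrid, sqrt(segB$area / segA$area)))
  shifts <- 0L
  if (params@maxShift > 0L) shifts <- c(0L, seq_len(params@maxShift),
                                        -seq_len(params@maxShift))
  best <- positionTerm(segA, segB)   # identity is always a member of H
  for (al in scales) {
    ry <- cA[1] + al * (yA - cA[1])
    rx <- cA[2] + al * (xA - cA[2])
    ## centroid-aligning translation, jittered along each axis in turn
    b0y <- cB[1] - mean(ry); b0x <- cB[2] - mean(rx)
    for (dy in shifts) {
      for (dx in shifts) {
        if (dy != 0L && dx != 0L) next  # axis-aligned jitter only
        py <- .rhalf(ry + b0y + dy)
        px <- .rhalf(rx + b0x + dx)
        idx <- unique((px - 1) * H + py)
        sc <- .pixelIoU(idx, segB$pixels)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

#' Shape term: best mask IoU over a scaling+translation search
#'
#' Each transformation scales segA's pixel set about its centroid and
#' translates it; the searched set is the configured scale grid plus the
#' pair's equivalent-diameter ratio, crossed with the centroid-aligning
#' translation jittered by up to \code{maxShift} px along each axis. The
#' identity transformation is always included, so
#' \code{shapeTerm >= positionTerm}. Two copies of the same shape score
#' (near) 1 regardless of how far apart they sit, which is what links thin
#' sheet-like structures that drift between slices.
#'
#' @inheritParams positionTerm
#' @param params a \linkS4class{LinkParams}.
#' @return best IoU in [0, 1].
#' @export
shapeTerm <- function(segA, segB, params = linkParams()) {
  .shapeCandidates(segA, segB, params, segA$dim[1L])
}

#' Refined similarity combining position and shape
#'
#' \eqn{(P^2 + \lambda S^2) / (1 + \lambda)} with P the position term and S
#' the shape term. At \code{lambda=0} it reduces to \eqn{P^2} (pure
#' overlap); as \code{lambda} grows the shape term dominates. Always in
#' [0, 1].
#'
#' @inheritParams shapeTerm
#' @return refined similarity in [0, 1].
#' @export
refinedSimilarity <- function(segA, segB, params = linkParams()) {
  P <- positionTerm(segA, segB)
  S <- if (params@lambda > 0) shapeTerm(segA, segB, params) else P
  (P^2 + params@lambda * S^2) / (1 + params@lambda)
}

#' Read / write linker parameters as YAML or JSON
#'
#' @param path file path; format chosen by extension (\code{.yaml},
#'   \code{.yml} or \code{.json}).
#' @return \code{readLinkParams}: a \linkS4class{LinkParams};
#'   \code{writeLinkParams}: the path, invisibly.
#' @export
readLinkParams <- function(path) {
  if (!file.exists(path)) stop("parameter file '", path, "' does not exist")
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  linkParams(Tl = x$Tl, Th = x$Th, Ts = x$Ts, lambda = x$lambda,
             scaleGrid = x$scaleGrid, maxShift = x$maxShift,
             skipEnabled = x$skipEnabled)
}

#' @rdname readLinkParams
#' @param params a \linkS4class{LinkParams} to serialize.
#' @export
writeLinkParams <- function(params, path) {
  x <- list(Tl = params@Tl, Th = params@Th, Ts = params@Ts,
            lambda = params@lambda, scaleGrid = params@scaleGrid,
            maxShift = params@maxShift, skipEnabled = params@skipEnabled)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
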