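## Synthetic slice stacks with known 3D ground truth.
##
## Objects are placed on a non-touching grid (>= 2 px separation, so
## per-slice 2D segmentation is unambiguous) and traced through all
## slices. Two shape families mirror the two regimes the linker has to
## cope with: "blob" cross-sections are filled ellipses with smoothly
## varying axes and small centroid jitter, which overlap strongly slice to
## slice (mitochondria-like); "sheet" cross-sections are thin elongated
## rectangles whose consecutive copies are translated along their long
## axis and overlap only a few pixels (synapse-like), so only the shape
## term can link them. Injected events: a split turns an object into two
## separated halves from a chosen slice onward, a merge is the mirror
## image, and a gap drops an object from exactly one interior slice.

#' Build and validate a synthetic scenario configuration
#'
#' @param nSlices,height,width stack geometry (slices, rows, cols).
#' @param nObjects number of 3D objects to generate.
#' @param shapeFamily \code{"blob"} or \code{"sheet"}.
#' @param pSplit,pMerge per-object probability of a split / merge event
#'   (an object receives at most one event).
#' @param nGaps number of single-slice dropouts, each injected into a
#'   distinct event-free object on an interior slice.
#' @param driftPx maximum per-slice centroid jitter in px.
#' @param scaleJitter maximum relative per-slice change of the blob axes.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated list of class \code{ScenarioConfig}.
#' @examples
#' cfg <- scenarioConfig(nSlices = 8, nObjects = 5, seed = 1)
#' @export
scenarioConfig <- function(nSlices = 10L, height = 128L, width = 128L,
                           nObjects = 10L, shapeFamily = c("blob", "sheet"),
                           pSplit = 0, pMerge = 0, nGaps = 0L,
                           driftPx = 1L, scaleJitter = 0.05, seed = 1L) {
  shapeFamily <- match.arg(shapeFamily)
  bad <- character(0)
  if (nSlices < 1) bad <- c(bad, "nSlices must be >= 1")
  if (height < 16 || width < 16) bad <- c(bad, "height/width must be >= 16")
  if (nObjects < 0) bad <- c(bad, "nObjects must be >= 0")
  if (pSplit < 0 || pSplit > 1) bad <- c(bad, "pSplit must lie in [0,1]")
  if (pMerge < 0 || pMerge > 1) bad <- c(bad, "pMerge must lie in [0,1]")
  if (pSplit + pMerge > 1) bad <- c(bad, "pSplit + pMerge must be <= 1")
  if (nGaps < 0) bad <- c(bad, "nGaps must be >= 0")
  if (driftPx < 0) bad <- c(bad, "driftPx must be >= 0")
  if (scaleJitter < 0 || scaleJitter > 0.25)
    bad <- c(bad, "scaleJitter must lie in [0, 0.25]")
  if (nGaps > 0 && nSlices < 5)
    bad <- c(bad, "gaps need nSlices >= 5 (interior slice, skip range)")
  if (length(bad)) stop("invalid scenario config: ", paste(bad, collapse = "; "))
  structure(list(nSlices = as.integer(nSlices), height = as.integer(height),
                 width = as.integer(width), nObjects = as.integer(nObjects),
                 shapeFamily = shapeFamily, pSplit = pSplit, pMerge = pMerge,
                 nGaps = as.integer(nGaps), driftPx = as.integer(driftPx),
                 scaleJitter = scaleJitter, seed = as.integer(seed)),
            class = "ScenarioConfig")
}

#' Read a scenario configuration from YAML or JSON
#' @param path config file; fields as in [scenarioConfig()].
#' @return a \code{ScenarioConfig}.
#' @export
readScenarioConfig <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(scenarioConfig, x)
}

## rasterize a filled ellipse; returns (y, x) integer matrix
.ellipsePixels <- function(cy, cx, ry, rx, H, W) {
  ys <- max(1L, floor(cy - ry)):min(H, ceiling(cy + ry))
  xs <- max(1L, floor(cx - rx)):min(W, ceiling(cx + rx))
  g <- expand.grid(y = ys, x = xs)
  keep <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

.rectPixels <- function(y0, x0, th, len, H, W) {
  ys <- y0:min(H, y0 + th - 1L)
  xs <- x0:min(W, x0 + len - 1L)
  as.matrix(expand.grid(y = ys, x = xs))
}

## halves of a pixel set split along x (or y), dropping a 1-px channel so
## the two pieces are not 8-connected
.splitHalves <- function(px, along = c("x", "y")) {
  along <- match.arg(along)
  v <- px[, along]
  mid <- round(mean(range(v)))
  list(px[v <= mid - 1L, , drop = FALSE], px[v >= mid + 1L, , drop = FALSE])
}

#' Generate a synthetic stack with known 3D ground truth
#'
#' Deterministic given the seed in the config. Objects span all slices;
#' split objects become two separated halves from the event slice onward,
#' merged objects are two halves that fuse at the event slice, and gap
#' objects are absent from exactly one interior slice. The ground-truth
#' grouping assigns every 2D segment to its generating 3D object, aligned
#' with the segment enumeration of [extractSegments()].
#'
#' @param config a \code{ScenarioConfig}.
#' @return list with \code{stack} (binary \linkS4class{SliceStack}),
#'   \code{truth} (a \linkS4class{Linked3D}), and \code{events}
#'   (data.frame with columns \code{event}, \code{object}, \code{slice}).
#' @export
generateStack <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- config$nSlices; H <- config$height; W <- config$width
  truthImg <- lapply(seq_len(n), function(i) matrix(0L, H, W))

  ## grid placement: one object per cell, jitter bounded by the cell pad
  if (config$shapeFamily == "blob") {
    maxR <- 7L
    side <- 2L * (maxR + config$driftPx) + 4L
    cellH <- side; cellW <- side
  } else {
    maxTh <- 6L; lenRange <- c(24L, 40L); ovRange <- c(3L, 6L)
    cellH <- maxTh + 2L * config$driftPx + 6L
    cellW <- 2L * lenRange[2L] + 4L
  }
  nRow <- H %/% cellH; nCol <- W %/% cellW
  if (config$nObjects > nRow * nCol)
    stop(sprintf(paste("cannot place %d non-touching objects on a %dx%d",
                       "frame; reduce nObjects (capacity %d) or enlarge",
                       "the frame"),
         config$nObjects, H, W, nRow * nCol))

  nObj <- config$nObjects
  if (config$nGaps > nObj)
    stop("nGaps exceeds nObjects; reduce nGaps")
  cells <- sample(nRow * nCol, nObj)
  ## gap objects are reserved first and kept event-free, so every gap
  ## contributes exactly one chain break
  gapObjs <- if (config$nGaps > 0L) sample(nObj, config$nGaps) else integer(0)
  u <- runif(nObj)
  eventType <- ifelse(u < config$pSplit, "split",
               ifelse(u < config$pSplit + config$pMerge, "merge", "none"))
  eventType[gapObjs] <- "none"
  if (n < 4L) eventType[] <- "none"   # no room for a distinct event slice

  events <- list()
  for (o in seq_len(nObj)) {
    cell <- cells[o] - 1L
    ry0 <- (cell %/% nCol) * cellH; cx0 <- (cell %% nCol) * cellW
    ev <- eventType[o]
    tEv <- if (ev != "none") sample(seq(max(2L, ceiling(n / 3)),
                                        max(2L, floor(2 * n / 3))), 1L) else NA_integer_
    tGap <- if (o %in% gapObjs) sample(seq(3L, n - 2L), 1L) else NA_integer_

    if (config$shapeFamily == "blob") {
      ry <- runif(1, 4, maxR - 0.2); rx <- runif(1, 4, maxR - 0.2)
      cy <- ry0 + cellH / 2; cx <- cx0 + cellW / 2
      for (t in seq_len(n)) {
        if (!is.na(tGap) && t == tGap) next
        jy <- if (config$driftPx > 0) sample(-config$driftPx:config$driftPx, 1L) else 0L
        jx <- if (config$driftPx > 0) sample(-config$driftPx:config$driftPx, 1L) else 0L
        sj <- 1 + runif(1, -config$scaleJitter, config$scaleJitter)
        px <- .ellipsePixels(cy + jy, cx + jx, ry * sj, rx * sj, H, W)
        twoPieces <- (ev == "split" && t >= tEv) ||
                     (ev == "merge" && t < tEv)
        if (twoPieces) {
          halves <- .splitHalves(px, "x")
          px <- rbind(halves[[1L]], halves[[2L]])
        }
        truthImg[[t]][px] <- o
      }
    } else {
      th <- sample(5:maxTh, 1L)                       # >= 5 so halves connect
      len <- sample(lenRange[1L]:lenRange[2L], 1L)
      ov <- sample(ovRange[1L]:ovRange[2L], 1L)       # few-px overlap
      shift <- len - ov
      yb <- ry0 + 1L + config$driftPx + 1L
      xb <- cx0 + 2L
      for (t in seq_len(n)) {
        if (!is.na(tGap) && t == tGap) next
        jy <- if (config$driftPx > 0) sample(-config$driftPx:config$driftPx, 1L) else 0L
        xo <- if (t %% 2L == 0L) shift else 0L        # zigzag along the axis
        px <- .rectPixels(yb + jy, xb + xo, th, len, H, W)
        twoPieces <- (ev == "split" && t >= tEv) ||
                     (ev == "merge" && t < tEv)
        if (twoPieces) {
          halves <- .splitHalves(px, "y")
          px <- rbind(halves[[1L]], halves[[2L]])
        }
        truthImg[[t]][px] <- o
      }
    }
    if (ev != "none")
      events[[length(events) + 1L]] <-
        data.frame(event = ev, object = o, slice = tEv)
    if (!is.na(tGap))
      events[[length(events) + 1L]] <-
        data.frame(event = "gap", object = o, slice = tGap)
  }

  masks <- lapply(truthImg, function(m) (m > 0L) * 1L)
  stack <- SliceStack(masks)
  segsBySlice <- .stackSegments(stack)
  segdf <- .segmentFrame(segsBySlice)
  pixels <- unlist(lapply(segsBySlice, function(sl)
    lapply(sl, `[[`, "pixels")), recursive = FALSE)
  if (is.null(pixels)) pixels <- list()
  truthLabels <- integer(nrow(segdf))
  gi <- 0L
  for (i in seq_along(segsBySlice)) {
    for (s in segsBySlice[[i]]) {
      gi <- gi + 1L
      truthLabels[gi] <- truthImg[[i]][s$pixels[1L]]
    }
  }
  truth <- new("Linked3D", segments = segdf, pixels = pixels,
               labels = truthLabels, dim = c(H, W), nSlices = as.integer(n),
               fineMatrices = list(),
               skipPairs = data.frame(from = integer(0), to = integer(0)),
               categories = list())
  eventLog <- if (length(events)) do.call(rbind, events)
  else data.frame(event = character(0), object = integer(0),
                  slice = integer(0))
  list(stack = stack, truth = truth, events = eventLog)
}
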