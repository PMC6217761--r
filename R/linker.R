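## Forward coarse-to-fine connection of per-slice segments into 3D objects.
##
## Stages: coarse bounding-box IoU matrices -> mask-level validation into
## binary fine matrices -> per-segment categories -> forward labeling with
## split/merge label re-assignment -> optional skip connection across one
## missing slice. The final partition equals the connected components of
## the segment graph whose edges are the fine-matrix 1s plus accepted skip
## pairs; the category machinery is a single forward pass over that graph.

.CATS <- c("O", "S", "E", "S1", "M1", "S2", "M2")

## mutable union-find over label values; union keeps the smaller root, so
## the root of a set is always its minimum label
.newUF <- function(n) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(n)
  e
}
.find <- function(e, i) {
  p <- e$parent
  while (p[i] != i) {
    p[i] <- p[p[i]]
    i <- p[i]
  }
  e$parent <- p
  i
}
.unite <- function(e, a, b) {
  ra <- .find(e, a); rb <- .find(e, b)
  if (ra != rb) e$parent[max(ra, rb)] <- min(ra, rb)
  invisible(NULL)
}

## sparse matrix entries as (i, j, x) triplets; coerce to general storage
## first so unit-diagonal/symmetric classes do not hide entries
.triplets <- function(M) {
  Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  keep <- Tm@x != 0
  data.frame(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L, x = Tm@x[keep])
}

## dense -> dgCMatrix without class specialization
.asSparse <- function(M) {
  nz <- which(M != 0, arr.ind = TRUE)
  Matrix::sparseMatrix(i = nz[, 1L], j = nz[, 2L], x = M[nz], dims = dim(M))
}

#' Coarse connection matrices from bounding-box IoU
#'
#' One sparse matrix per slice pair \code{(i, i+gap)}; entry \code{(p, q)}
#' is the bounding-box IoU of segment p on slice i and segment q on slice
#' i+gap, with exact zeros (disjoint boxes) omitted. \code{gap=1} gives the
#' adjacent-slice matrices, \code{gap=2} the skip-candidate matrices.
#'
#' @param segsBySlice list (one element per slice) of segment lists from
#'   [extractSegments()].
#' @param gap 1 (adjacent) or 2 (skip).
#' @return list of \code{dgCMatrix}, length \code{n - gap}.
#' @export
coarseMatrices <- function(segsBySlice, gap = 1L) {
  n <- length(segsBySlice)
  gap <- as.integer(gap)
  stopifnot(gap %in% c(1L, 2L))
  if (n <= gap) return(list())
  lapply(seq_len(n - gap), function(i)
    .asSparse(.bboxIoUAll(segsBySlice[[i]], segsBySlice[[i + gap]])))
}

#' Validate a coarse matrix into a binary fine-connection matrix
#'
#' Entries at or above \code{Th} connect without validation; entries below
#' \code{Tl} are dropped; in-between entries are replaced by the refined
#' similarity (position + shape) and connect when strictly above \code{Ts}.
#'
#' @param C sparse coarse matrix for slices \code{(i, i+1)}.
#' @param segsI,segsJ segment lists of the two slices.
#' @param params a \linkS4class{LinkParams}.
#' @return binary sparse matrix of the same shape.
#' @export
refineMatrix <- function(C, segsI, segsJ, params) {
  tr <- .triplets(C)
  keep <- logical(nrow(tr))
  for (r in seq_len(nrow(tr))) {
    cls <- classifyCoarse(tr$x[r], params)
    keep[r] <- switch(cls,
      CONNECT = TRUE,
      NONE = FALSE,
      VALIDATE = refinedSimilarity(segsI[[tr$i[r]]], segsJ[[tr$j[r]]],
                                   params) > params@Ts)
  }
  Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep],
                       x = rep(1, sum(keep)), dims = dim(C))
}

## coerce user-supplied binary matrices (base or Matrix) to dgCMatrix list
.asBinaryList <- function(Blist) {
  lapply(Blist, function(B) .asSparse((as.matrix(B) > 0) * 1))
}

#' Assign connection categories to every segment
#'
#' From each binary matrix \code{B[[i]]} with row sums R (connections a
#' slice-i segment makes forward) and column sums N (connections a
#' slice-(i+1) segment receives): a row with R=0 is an End, with R>=2 a
#' Split1 parent; a column with N=0 is a Start, with N>=2 a Merge2 child.
#' Each edge (p,q) additionally marks p as One-to-one (R=1, N=1) or Merge1
#' (R=1, N>=2), and q as Split2 (R>=2, N=1). Every segment on the first
#' slice is a Start and every segment on the last slice an End. A segment
#' may hold several categories.
#'
#' @param Blist list of n-1 binary adjacent-slice matrices (base matrices
#'   accepted).
#' @return list of n logical matrices (k_i x 7, columns
#'   \code{O,S,E,S1,M1,S2,M2}).
#' @export
assignCategories <- function(Blist) {
  stopifnot(length(Blist) >= 1L)
  Blist <- .asBinaryList(Blist)
  n <- length(Blist) + 1L
  k <- c(vapply(Blist, nrow, integer(1)), ncol(Blist[[length(Blist)]]))
  cats <- lapply(k, function(ki)
    matrix(FALSE, ki, 7L, dimnames = list(NULL, .CATS)))
  for (i in seq_len(n - 1L)) {
    B <- Blist[[i]]
    R <- Matrix::rowSums(B)
    N <- Matrix::colSums(B)
    cats[[i]][R == 0, "E"] <- TRUE
    cats[[i]][R >= 2, "S1"] <- TRUE
    cats[[i + 1L]][N == 0, "S"] <- TRUE
    cats[[i + 1L]][N >= 2, "M2"] <- TRUE
    e <- .triplets(B)
    for (r in seq_len(nrow(e))) {
      p <- e$i[r]; q <- e$j[r]
      if (R[p] == 1 && N[q] == 1) cats[[i]][p, "O"] <- TRUE
      if (R[p] == 1 && N[q] >= 2) cats[[i]][p, "M1"] <- TRUE
      if (R[p] >= 2 && N[q] == 1) cats[[i + 1L]][q, "S2"] <- TRUE
    }
  }
  if (k[1L] > 0L) cats[[1L]][, "S"] <- TRUE
  if (k[n] > 0L) cats[[n]][, "E"] <- TRUE
  cats
}

## global segment id helpers: ids are assigned slice by slice
.gidOffsets <- function(k) c(0L, cumsum(k))[seq_along(k)]

#' Forward labeling with split/merge re-assignment
#'
#' Seeds (segments carrying Start, Split2 or Merge2) receive fresh labels
#' in (slice, segment) order; labels propagate forward along one-to-one
#' chains; then every Split1/Merge1 segment has its label united with the
#' labels of its connected Split2/Merge2 partners on the next slice, each
#' group keeping its minimum label (transitive closure via union-find over
#' label values). The result partitions all segments and equals the
#' connected components of the graph whose edges are the fine-matrix 1s.
#'
#' @inheritParams assignCategories
#' @param categories optional precomputed [assignCategories()] output.
#' @return list with \code{labels} (final label per global segment id: the
#'   minimum seed label of its group), \code{initial} (labels before
#'   re-assignment), \code{k} (segments per slice), and \code{uf} (the
#'   union-find over label values, consumed by [skipConnect()]).
#' @export
forwardLabel <- function(Blist, categories = NULL) {
  BlistC <- .asBinaryList(Blist)
  n <- length(BlistC) + 1L
  k <- c(vapply(BlistC, nrow, integer(1)), ncol(BlistC[[length(BlistC)]]))
  if (is.null(categories)) categories <- assignCategories(BlistC)
  off <- .gidOffsets(k)
  total <- sum(k)
  initial <- rep(NA_integer_, total)
  nextLab <- 1L

  ## seed every Start/Split2/Merge2 segment, in deterministic order
  for (i in seq_len(n)) {
    for (p in seq_len(k[i])) {
      if (any(categories[[i]][p, c("S", "S2", "M2")])) {
        initial[off[i] + p] <- nextLab
        nextLab <- nextLab + 1L
      }
    }
  }

  ## propagate along one-to-one chains
  for (i in seq_len(n)) {
    for (p in seq_len(k[i])) {
      gid <- off[i] + p
      if (is.na(initial[gid])) next
      ci <- i; cp <- p
      while (ci < n && categories[[ci]][cp, "O"]) {
        q <- which(as.numeric(BlistC[[ci]][cp, , drop = TRUE]) > 0)
        initial[off[ci + 1L] + q] <- initial[gid]
        cp <- q; ci <- ci + 1L
      }
    }
  }
  if (anyNA(initial))
    stop("internal consistency error: segment left unlabeled after forward pass")

  ## split/merge re-assignment over label values
  uf <- .newUF(max(nextLab - 1L, 1L))
  for (i in seq_len(n - 1L)) {
    if (k[i] == 0L) next
    e <- .triplets(BlistC[[i]])
    for (r in seq_len(nrow(e))) {
      p <- e$i[r]; q <- e$j[r]
      if (categories[[i]][p, "M1"] || categories[[i]][p, "S1"])
        .unite(uf, initial[off[i] + p], initial[off[i + 1L] + q])
    }
  }
  labels <- vapply(initial, function(j) .find(uf, j), integer(1))
  list(labels = labels, initial = initial, k = k, uf = uf)
}

#' Skip connection across one missing slice
#'
#' For every pair of an ending segment on slice i (no forward connection in
#' \code{B[[i]]}) and a starting segment on slice i+2 (no incoming
#' connection in \code{B[[i+1]]}) whose bounding boxes overlap, the refined
#' similarity is computed; pairs scoring strictly above \code{Ts} have
#' their labels united (minimum kept). Bridges single damaged or missing
#' slices; larger gaps are not considered.
#'
#' @param fl result of [forwardLabel()].
#' @param segsBySlice per-slice segment lists.
#' @param categories [assignCategories()] output used for the forward pass.
#' @param params a \linkS4class{LinkParams}.
#' @return list with updated \code{labels} and \code{accepted} (data.frame
#'   of united global segment id pairs).
#' @export
skipConnect <- function(fl, segsBySlice, categories, params) {
  n <- length(segsBySlice)
  k <- fl$k
  off <- .gidOffsets(k)
  acc <- list()
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (k[i] == 0L || k[i + 2L] == 0L) next
      ends <- which(categories[[i]][, "E"])
      starts <- which(categories[[i + 2L]][, "S"])
      if (!length(ends) || !length(starts)) next
      C2 <- .bboxIoUAll(segsBySlice[[i]], segsBySlice[[i + 2L]])
      for (p in ends) for (q in starts) {
        if (C2[p, q] > 0) {
          cs <- refinedSimilarity(segsBySlice[[i]][[p]],
                                  segsBySlice[[i + 2L]][[q]], params)
          if (cs > params@Ts) {
            .unite(fl$uf, fl$initial[off[i] + p],
                   fl$initial[off[i + 2L] + q])
            acc[[length(acc) + 1L]] <- c(from = off[i] + p,
                                         to = off[i + 2L] + q)
          }
        }
      }
    }
  }
  accepted <- if (length(acc)) as.data.frame(do.call(rbind, acc))
  else data.frame(from = integer(0), to = integer(0))
  labels <- vapply(fl$initial, function(j) .find(fl$uf, j), integer(1))
  list(labels = labels, accepted = accepted)
}

#' Run the full coarse-to-fine 3D connection pipeline
#'
#' Extract segments -> coarse bounding-box matrices -> validation into
#' binary fine matrices -> categories -> forward labeling -> skip
#' connection (if enabled). Returns the partition of all 2D segments into
#' 3D objects together with the intermediate structures.
#'
#' @param stack a \linkS4class{SliceStack}.
#' @param params a \linkS4class{LinkParams}.
#' @return a \linkS4class{Linked3D}.
#' @examples
#' s <- matrix(0L, 16, 16); s[4:8, 4:8] <- 1L
#' stk <- SliceStack(list(s, s, s))
#' linkStack(stk)
#' @export
linkStack <- function(stack, params = linkParams()) {
  stopifnot(is(stack, "SliceStack"), is(params, "LinkParams"))
  segsBySlice <- .stackSegments(stack)
  n <- length(segsBySlice)
  k <- vapply(segsBySlice, length, integer(1))
  segdf <- .segmentFrame(segsBySlice)
  pixels <- unlist(lapply(segsBySlice, function(sl)
    lapply(sl, `[[`, "pixels")), recursive = FALSE)
  if (is.null(pixels)) pixels <- list()

  if (sum(k) == 0L || n == 1L) {
    labels <- if (sum(k)) seq_len(sum(k)) else integer(0)
    return(new("Linked3D", segments = segdf, pixels = pixels,
               labels = as.integer(labels), dim = sliceDim(stack),
               nSlices = as.integer(n), fineMatrices = list(),
               skipPairs = data.frame(from = integer(0), to = integer(0)),
               categories = list()))
  }

  Clist <- coarseMatrices(segsBySlice, gap = 1L)
  Blist <- lapply(seq_along(Clist), function(i)
    refineMatrix(Clist[[i]], segsBySlice[[i]], segsBySlice[[i + 1L]], params))
  categories <- assignCategories(Blist)
  fl <- forwardLabel(Blist, categories)
  if (params@skipEnabled) {
    sk <- skipConnect(fl, segsBySlice, categories, params)
    labels <- sk$labels
    skipPairs <- sk$accepted
  } else {
    labels <- fl$labels
    skipPairs <- data.frame(from = integer(0), to = integer(0))
  }
  new("Linked3D", segments = segdf, pixels = pixels,
      labels = as.integer(labels), dim = sliceDim(stack),
      nSlices = as.integer(n), fineMatrices = Blist,
      skipPairs = skipPairs, categories = categories)
}

## flat data.frame over all segments of a stack
.segmentFrame <- function(segsBySlice) {
  rows <- unlist(lapply(segsBySlice, function(sl) lapply(sl, function(s)
    data.frame(slice = s$slice, seg = s$seg, area = s$area,
               y0 = s$bbox[[1]], x0 = s$bbox[[2]], y1 = s$bbox[[3]],
               x1 = s$bbox[[4]], cy = s$centroid[[1]], cx = s$centroid[[2]]))),
    recursive = FALSE)
  if (is.null(rows) || !length(rows))
    return(data.frame(slice = integer(0), seg = integer(0),
                      area = integer(0), y0 = integer(0), x0 = integer(0),
                      y1 = integer(0), x1 = integer(0), cy = numeric(0),
                      cx = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-object statistics table
#'
#' One row per final 3D label: member segment count, voxel count, physical
#' volume (voxel count times the voxel's nm^3), and first/last slice.
#'
#' @param linked a \linkS4class{Linked3D}.
#' @param voxelSize numeric(3) voxel edge lengths in nm.
#' @return data.frame with columns \code{label, nSegments, voxelCount,
#'   volumeNm3, zFirst, zLast}.
#' @export
objectTable <- function(linked, voxelSize = c(2, 2, 50)) {
  segs <- linked@segments
  if (!nrow(segs))
    return(data.frame(label = integer(0), nSegments = integer(0),
                      voxelCount = integer(0), volumeNm3 = numeric(0),
                      zFirst = integer(0), zLast = integer(0)))
  sp <- split(seq_len(nrow(segs)), linked@labels)
  vx <- prod(voxelSize)
  out <- do.call(rbind, lapply(names(sp), function(lb) {
    ii <- sp[[lb]]
    data.frame(label = as.integer(lb), nSegments = length(ii),
               voxelCount = sum(segs$area[ii]),
               volumeNm3 = sum(segs$area[ii]) * vx,
               zFirst = min(segs$slice[ii]), zLast = max(segs$slice[ii]))
  }))
  out[order(out$label), , drop = FALSE]
}
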