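## Per-slice 2D component extraction and bounding-box IoU.
##
## Segments are connected foreground regions under 8-connectivity. Bounding
## boxes are tight and half-open: c(y0, x0, y1, x1) covers rows [y0, y1) and
## columns [x0, x1) in 1-based pixel coordinates, so the area is
## (y1-y0)*(x1-x0).

.ufClosure <- function(n, pairs) {
  ## pairs: 2-column integer matrix of indices to union; returns root per id
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so close the
## diagonal adjacencies with a union-find over label pairs.
.label8 <- function(bin) {
  L <- EBImage::bwlabel(bin)
  L <- matrix(as.integer(L), nrow(bin), ncol(bin))
  k <- max(L)
  if (k < 2L) return(L)
  H <- nrow(L); W <- ncol(L)
  a1 <- L[-H, -1L]; b1 <- L[-1L, -W]   # down-left diagonal
  a2 <- L[-H, -W];  b2 <- L[-1L, -1L]  # down-right diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (!nrow(pairs)) return(L)
  root <- .ufClosure(k, pairs)
  L[L > 0L] <- root[L[L > 0L]]
  L
}

#' Extract 2D segments from one slice mask
#'
#' Binary masks are decomposed into 8-connected components; pre-labeled
#' masks yield one segment per distinct nonzero value, with disconnected
#' values split into their components. Segments are ordered by the
#' row-major scan position of their first foreground pixel, which fixes the
#' row/column indices of all connection matrices.
#'
#' @param mask non-negative integer matrix; 0 is background.
#' @param sliceIndex integer recorded on every returned segment.
#' @return list of segments; each is a list with elements \code{slice},
#'   \code{seg}, \code{pixels} (sorted linear indices, column-major),
#'   \code{area}, \code{bbox} (half-open \code{c(y0,x0,y1,x1)}) and
#'   \code{centroid} (\code{c(cy,cx)}). An all-zero mask gives
#'   \code{list()}.
#' @examples
#' m <- matrix(0L, 32, 32)
#' m[1:5, 1:5] <- 1L; m[21:25, 21:25] <- 1L
#' length(extractSegments(m, 1L))
#' @export
extractSegments <- function(mask, sliceIndex = 1L) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("mask values must be non-negative")
  storage.mode(mask) <- "integer"
  vals <- unique(mask[mask > 0L])
  if (!length(vals)) return(list())
  H <- nrow(mask); W <- ncol(mask)
  if (length(vals) == 1L) {
    L <- .label8(mask > 0L)
  } else {
    ## labeled dialect: components within each value, with disjoint codes
    L <- matrix(0L, H, W)
    offset <- 0L
    for (v in sort(vals)) {
      Lv <- .label8(mask == v)
      sel <- Lv > 0L
      L[sel] <- Lv[sel] + offset
      offset <- offset + max(Lv)
    }
  }
  idx <- which(L > 0L)
  grp <- split(idx, L[idx])
  y <- ((idx - 1L) %% H) + 1L
  x <- ((idx - 1L) %/% H) + 1L
  scan <- (y - 1L) * W + x                  # row-major rank
  firstScan <- vapply(split(scan, L[idx]), min, numeric(1))
  ord <- order(firstScan)
  grp <- grp[ord]
  out <- vector("list", length(grp))
  for (s in seq_along(grp)) {
    px <- sort(grp[[s]])
    py <- ((px - 1L) %% H) + 1L
    pxc <- ((px - 1L) %/% H) + 1L
    out[[s]] <- list(
      slice = as.integer(sliceIndex), seg = s, pixels = px,
      dim = c(H, W), area = length(px),
      bbox = c(y0 = min(py), x0 = min(pxc),
               y1 = max(py) + 1L, x1 = max(pxc) + 1L),
      centroid = c(cy = mean(py), cx = mean(pxc)))
  }
  out
}

## Extract segments for every slice of a stack; returns list per slice.
.stackSegments <- function(stack) {
  lapply(seq_along(stack@masks),
         function(i) extractSegments(stack@masks[[i]], i))
}

#' Intersection-over-union of two bounding boxes
#'
#' Boxes are half-open \code{c(y0, x0, y1, x1)}. Disjoint boxes score 0;
#' because every segment lies inside its box, a zero box IoU guarantees the
#' segments themselves are disjoint, which is what makes the box a sound
#' prefilter for the expensive mask comparison.
#'
#' @param a,b numeric(4) half-open boxes.
#' @return IoU in [0, 1].
#' @examples
#' bboxIoU(c(1, 1, 11, 11), c(1, 6, 11, 16))  # 1/3
#' @export
bboxIoU <- function(a, b) {
  iy <- min(a[3], b[3]) - max(a[1], b[1])
  ix <- min(a[4], b[4]) - max(a[2], b[2])
  if (iy <= 0 || ix <= 0) return(0)
  inter <- iy * ix
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

## vectorized all-pairs box IoU between two segment lists -> dense matrix
.bboxIoUAll <- function(segsA, segsB) {
  ka <- length(segsA); kb <- length(segsB)
  if (ka == 0L || kb == 0L) return(matrix(0, ka, kb))
  A <- t(vapply(segsA, `[[`, numeric(4), "bbox"))
  B <- t(vapply(segsB, `[[`, numeric(4), "bbox"))
  y0 <- outer(A[, 1], B[, 1], pmax); y1 <- outer(A[, 3], B[, 3], pmin)
  x0 <- outer(A[, 2], B[, 2], pmax); x1 <- outer(A[, 4], B[, 4], pmin)
  ih <- pmax(y1 - y0, 0); iw <- pmax(x1 - x0, 0)
  inter <- ih * iw
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, `+`) - inter)
}
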