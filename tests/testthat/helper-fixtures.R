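# shared fixtures and independent oracles for the test suite

# canonical form of a labeling: relabel by order of first appearance, so
# two partitions compare equal exactly when they group identically
canon <- function(labels) as.integer(factor(labels, levels = unique(labels)))

samePartition <- function(a, b) identical(canon(a), canon(b))

# one segment cut out of a mask matrix
segFromMask <- function(mask, which = 1L, slice = 1L) {
  extractSegments(mask, slice)[[which]]
}

squareMask <- function(H, W, y, x, side, value = 1L) {
  m <- matrix(0L, H, W)
  m[y:(y + side - 1L), x:(x + side - 1L)] <- value
  m
}

# brute-force box IoU by counting unit pixels on the union grid
bboxIoUBrute <- function(a, b) {
  ys <- min(a[1], b[1]):(max(a[3], b[3]) - 1L)
  xs <- min(a[2], b[2]):(max(a[4], b[4]) - 1L)
  g <- expand.grid(y = ys, x = xs)
  inA <- g$y >= a[1] & g$y < a[3] & g$x >= a[2] & g$x < a[4]
  inB <- g$y >= b[1] & g$y < b[3] & g$x >= b[2] & g$x < b[4]
  if (!any(inA & inB)) return(0)
  sum(inA & inB) / sum(inA | inB)
}

# brute-force mask IoU by pixel counting on a common grid
pixelIoUBrute <- function(maskA, maskB) {
  inter <- sum(maskA > 0 & maskB > 0)
  uni <- sum(maskA > 0 | maskB > 0)
  if (uni == 0) return(0)
  inter / uni
}

# exhaustive dense-grid maximization of the position term over scalings
# about segA's centroid and real-valued translations; independent of the
# package's transformation search
shapeTermDense <- function(segA, segB, alphas = seq(0.7, 1.3, by = 0.01),
                           deltas = seq(-2, 2, by = 0.5)) {
  H <- segA$dim[1L]
  yA <- ((segA$pixels - 1L) %% H) + 1L
  xA <- ((segA$pixels - 1L) %/% H) + 1L
  cA <- segA$centroid; cB <- segB$centroid
  rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)
  best <- 0
  for (al in alphas) {
    ry <- cA[1] + al * (yA - cA[1]); rx <- cA[2] + al * (xA - cA[2])
    b0y <- cB[1] - mean(ry); b0x <- cB[2] - mean(rx)
    for (dy in deltas) for (dx in deltas) {
      py <- rhalf(ry + b0y + dy); px <- rhalf(rx + b0x + dx)
      idx <- unique((px - 1) * H + py)
      ni <- sum(idx %in% segB$pixels)
      sc <- ni / (length(idx) + length(segB$pixels) - ni)
      if (sc > best) best <- sc
    }
  }
  best
}

# connected components of the segment graph implied by a Linked3D's own
# fine matrices and accepted skip pairs (igraph-based reference)
graphCCLabels <- function(lk) {
  segdf <- segmentTable(lk)
  nseg <- nrow(segdf)
  kTab <- table(factor(segdf$slice, levels = seq_len(lk@nSlices)))
  off <- c(0L, cumsum(as.integer(kTab)))
  edges <- integer(0)
  for (i in seq_along(lk@fineMatrices)) {
    M <- as.matrix(lk@fineMatrices[[i]])
    nz <- which(M > 0, arr.ind = TRUE)
    if (nrow(nz))
      edges <- c(edges, rbind(off[i] + nz[, 1L], off[i + 1L] + nz[, 2L]))
  }
  if (nrow(lk@skipPairs))
    edges <- c(edges, rbind(lk@skipPairs$from, lk@skipPairs$to))
  g <- igraph::make_empty_graph(nseg, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# the printed five-case binary connection matrix (rows: slice i segments,
# columns: slice i+1 segments)
fiveCaseMatrix <- function() {
  B <- matrix(0, 5, 5)
  B[1, 1] <- 1; B[3, 2] <- 1; B[3, 3] <- 1; B[4, 5] <- 1; B[5, 5] <- 1
  B
}
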