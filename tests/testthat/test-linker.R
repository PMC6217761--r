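test_that("coarse matrices hold bbox IoU with zeros omitted", {
  s1 <- matrix(0L, 32, 32); s1[5:14, 5:14] <- 1L; s1[20:24, 20:24] <- 1L
  s2 <- matrix(0L, 32, 32); s2[5:14, 5:14] <- 1L
  segs <- list(extractSegments(s1, 1L), extractSegments(s2, 2L))
  C <- coarseMatrices(segs)[[1]]
  expect_equal(dim(C), c(2L, 1L))
  expect_equal(C[1, 1], 1.0)      # identical boxes
  expect_equal(C[2, 1], 0)        # disjoint boxes stay structural zero
  expect_equal(Matrix::nnzero(C), 1L)

  # no overlapping boxes anywhere -> all matrices empty
  s3 <- matrix(0L, 32, 32); s3[26:30, 2:6] <- 1L
  segs2 <- list(extractSegments(s1, 1L), extractSegments(s3, 2L))
  expect_equal(Matrix::nnzero(coarseMatrices(segs2)[[1]]), 0L)
})

test_that("validation keeps CONNECT entries, eliminates false VALIDATE entries", {
  p <- linkParams()
  # two horizontally adjacent squares on slice i vs one shifted square on
  # slice i+1: box IoU in [Tl, Th) for the far pair, whose masks are
  # disjoint -> refined similarity small -> eliminated
  s1 <- matrix(0L, 64, 64)
  s1[10:19, 10:19] <- 1L
  s2 <- matrix(0L, 64, 64)
  s2[10:19, 24:33] <- 1L   # boxes disjoint from first square
  segsA <- extractSegments(s1, 1L); segsB <- extractSegments(s2, 2L)
  C <- coarseMatrices(list(segsA, segsB))[[1]]
  expect_equal(Matrix::nnzero(C), 0L)

  # entry >= Th connects without validation even where validation would
  # reject: full square vs its hollow ring share the box (IoU 1) but have
  # mask IoU 0.36, below this Ts
  m1 <- squareMask(32, 32, 5, 5, 10)
  m2 <- matrix(0L, 32, 32); m2[5:14, 5:14] <- 1L; m2[7:12, 7:12] <- 0L
  sa <- extractSegments(m1, 1L); sb <- extractSegments(m2, 2L)
  Cs <- coarseMatrices(list(sa, sb))
  pRing <- linkParams(lambda = 0, Ts = 0.2, Th = 0.4)
  B <- refineMatrix(Cs[[1]], sa, sb, pRing)
  expect_equal(B[1, 1], 1)

  # strict inequality: refined similarity exactly Ts does not connect
  pEdge <- linkParams(Ts = 1 / 9, lambda = 0)
  a <- segFromMask(squareMask(32, 32, 5, 5, 10), slice = 1L)
  s <- extractSegments(squareMask(32, 32, 5, 10, 10), 2L)  # P = 1/3, P^2 = 1/9
  C2 <- coarseMatrices(list(list(a), s))[[1]]
  B2 <- refineMatrix(C2, list(a), s, pEdge)
  expect_equal(Matrix::nnzero(B2), 0L)
})

test_that("the printed five-case matrix yields the printed categories and sums", {
  B <- fiveCaseMatrix()
  expect_equal(unname(rowSums(B)), c(1, 0, 2, 1, 1))   # R values
  expect_equal(unname(colSums(B)), c(1, 1, 1, 0, 2))   # N values
  cats <- assignCategories(list(B))
  rowCats <- cats[[1]]; colCats <- cats[[2]]
  expect_true(rowCats[1, "O"]);  expect_true(rowCats[2, "E"])
  expect_true(rowCats[3, "S1"]); expect_true(rowCats[4, "M1"])
  expect_true(rowCats[5, "M1"])
  expect_true(colCats[2, "S2"]); expect_true(colCats[3, "S2"])
  expect_true(colCats[4, "S"]);  expect_true(colCats[5, "M2"])
  expect_false(colCats[1, "S2"] || colCats[1, "M2"] || colCats[1, "S"])
  # boundary rules: first slice all Start, last slice all End
  expect_true(all(rowCats[, "S"]))
  expect_true(all(colCats[, "E"]))
})

test_that("degenerate matrices give the forced categories", {
  Bz <- matrix(0, 3, 4)
  cats <- assignCategories(list(Bz))
  expect_true(all(cats[[1]][, "E"]))
  expect_true(all(cats[[2]][, "S"]))
  Bi <- diag(3)
  cats2 <- assignCategories(list(Bi))
  expect_true(all(cats2[[1]][, "O"]))
  expect_false(any(cats2[[1]][, c("S1", "M1")]))
  expect_false(any(cats2[[2]][, c("S2", "M2")]))
})

test_that("forward labeling reproduces the five-object partition of the worked example", {
  fl <- forwardLabel(list(fiveCaseMatrix()))
  # graph-CC oracle: components of the bipartite edge set
  expect_true(samePartition(
    fl$labels, c(1, 2, 3, 4, 4, 1, 3, 3, 5, 4)))
  expect_equal(length(unique(fl$labels)), 5L)
  # single O chain across many slices -> one label
  n <- 6
  fl2 <- forwardLabel(rep(list(matrix(1, 1, 1)), n - 1))
  expect_equal(length(unique(fl2$labels)), 1L)
  # all-empty matrices -> every segment its own label
  fl3 <- forwardLabel(rep(list(matrix(0, 3, 3)), 2))
  expect_equal(length(unique(fl3$labels)), 9L)
})

test_that("skip connection bridges gaps only for End/Start pairs with overlap", {
  p <- linkParams()
  sq <- squareMask(32, 32, 5, 5, 10)
  blank <- matrix(0L, 32, 32)
  # identical masks around an empty slice -> single object after skip
  lk <- linkStack(SliceStack(list(sq, blank, sq)), p)
  expect_equal(nObjects(lk), 1L)
  expect_equal(nrow(lk@skipPairs), 1L)
  # same stack with skip disabled -> two objects
  lkOff <- linkStack(SliceStack(list(sq, blank, sq)),
                     linkParams(skipEnabled = FALSE))
  expect_equal(nObjects(lkOff), 2L)
  # no box overlap in slice i+2 -> unchanged
  far <- squareMask(32, 32, 20, 20, 10)
  lk2 <- linkStack(SliceStack(list(sq, blank, far)), p)
  expect_equal(nObjects(lk2), 2L)
  expect_equal(nrow(lk2@skipPairs), 0L)
  # overlapping candidate that is not a Start on slice i+2 stays untouched:
  # the i+2 segment continues an O chain running on slices 2..3
  other <- squareMask(32, 32, 5, 5, 10)
  lk3 <- linkStack(SliceStack(list(sq, blank, other, other)), p)
  expect_equal(nObjects(lk3), 1L)   # slice-3 segment is a Start: bridges
  # with slice 2 occupied the slice-3 segment continues an O chain, so it
  # is no longer a Start and no skip pair is considered
  lk4 <- linkStack(SliceStack(list(sq, sq, other, other)), p)
  expect_equal(nrow(lk4@skipPairs), 0L)
  expect_equal(nObjects(lk4), 1L)
})

test_that("pipeline partition equals graph components of its own matrices", {
  skip_if_not_installed("igraph")
  for (sd in 1:12) {
    cfg <- scenarioConfig(nSlices = 10, height = 96, width = 96,
                          nObjects = 5, pSplit = 0.3, pMerge = 0.3,
                          nGaps = 1, driftPx = 1, seed = 500 + sd)
    sim <- generateStack(cfg)
    lk <- linkStack(sim$stack, linkParams())
    expect_true(samePartition(segmentLabels(lk), graphCCLabels(lk)))
  }
})

test_that("identical inputs give identical labels and thresholds act monotonically", {
  cfg <- scenarioConfig(nSlices = 10, height = 96, width = 96, nObjects = 5,
                        pSplit = 0.3, driftPx = 2, seed = 77)
  sim <- generateStack(cfg)
  a <- linkStack(sim$stack, linkParams())
  b <- linkStack(sim$stack, linkParams())
  expect_identical(segmentLabels(a), segmentLabels(b))
  # raising Ts never decreases the number of objects
  counts <- vapply(c(0.01, 0.03, 0.1, 0.3), function(ts)
    nObjects(linkStack(sim$stack, linkParams(Ts = ts))), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pipeline handles empty and single-slice stacks", {
  blank <- matrix(0L, 16, 16)
  lk <- linkStack(SliceStack(list(blank, blank)))
  expect_equal(nObjects(lk), 0L)
  one <- squareMask(16, 16, 3, 3, 5)
  lk1 <- linkStack(SliceStack(list(one)))
  expect_equal(nObjects(lk1), 1L)
})

test_that("object table aggregates voxel counts, spans and physical volume", {
  s <- matrix(0L, 32, 32); s[3:12, 3:12] <- 1L   # 100 px per slice
  lk <- linkStack(SliceStack(list(s, s, s)))
  tab <- objectTable(lk, voxelSize = c(2, 2, 50))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$voxelCount, 300L)
  expect_equal(tab$volumeNm3, 60000)
  expect_equal(tab$zFirst, 1L); expect_equal(tab$zLast, 3L)
  # voxel total equals foreground pixel count
  expect_equal(sum(tab$voxelCount), 3L * 100L)
})
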