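test_that("coarse screening splits [0,1] into the three printed intervals", {
  p <- linkParams(Tl = 0.01, Th = 0.4)
  expect_identical(classifyCoarse(0.50, p), "CONNECT")
  expect_identical(classifyCoarse(0.005, p), "NONE")
  expect_identical(classifyCoarse(0.20, p), "VALIDATE")
  # endpoints: closed at Th, half-open elsewhere
  expect_identical(classifyCoarse(0.4, p), "CONNECT")
  expect_identical(classifyCoarse(0.01, p), "VALIDATE")
  expect_identical(classifyCoarse(0, p), "NONE")
  expect_identical(classifyCoarse(1, p), "CONNECT")
  expect_error(classifyCoarse(1.2, p), "\\[0, 1\\]")
  expect_error(classifyCoarse(-0.1, p), "\\[0, 1\\]")
})

test_that("position term equals the brute-force mask IoU", {
  a <- segFromMask(squareMask(32, 32, 5, 5, 10))
  expect_equal(positionTerm(a, a), 1.0)
  b <- segFromMask(squareMask(32, 32, 20, 20, 5))
  expect_equal(positionTerm(a, b), 0.0)
  # 10x10 square shifted 5 px in x: 50 / 150
  s <- segFromMask(squareMask(32, 32, 5, 10, 10))
  expect_equal(positionTerm(a, s), 1 / 3)

  set.seed(3)
  for (rep in 1:10) {
    mA <- matrix(rbinom(24 * 24, 1, 0.4), 24, 24)
    mB <- matrix(rbinom(24 * 24, 1, 0.4), 24, 24)
    segsA <- extractSegments(mA); segsB <- extractSegments(mB)
    if (!length(segsA) || !length(segsB)) next
    sa <- segsA[[1]]; sb <- segsB[[1]]
    ra <- matrix(0L, 24, 24); ra[sa$pixels] <- 1L
    rb <- matrix(0L, 24, 24); rb[sb$pixels] <- 1L
    expect_equal(positionTerm(sa, sb), pixelIoUBrute(ra, rb))
  }
})

test_that("shape term finds translated and scaled copies", {
  p <- linkParams()
  # same square far away: translation alignment recovers IoU 1 while the
  # position term is 0
  a <- segFromMask(squareMask(48, 48, 5, 5, 10))
  b <- segFromMask(squareMask(48, 48, 30, 30, 10))
  expect_equal(positionTerm(a, b), 0)
  expect_equal(shapeTerm(a, b, p), 1.0)

  # identical shape, small offset: centroid alignment gives 1
  c1 <- segFromMask(squareMask(48, 48, 5, 5, 11))
  c2 <- segFromMask(squareMask(48, 48, 8, 9, 11))
  expect_equal(shapeTerm(c1, c2, p), 1.0)

  # scaled copy: matches the exhaustive dense-grid oracle within
  # resampling tolerance
  e1 <- matrix(0L, 48, 48); e2 <- matrix(0L, 48, 48)
  for (y in 1:48) for (x in 1:48) {
    if (((y - 20) / 8)^2 + ((x - 20) / 10)^2 <= 1) e1[y, x] <- 1L
    if (((y - 24) / (8 * 0.9))^2 + ((x - 26) / (10 * 0.9))^2 <= 1) e2[y, x] <- 1L
  }
  sa <- segFromMask(e1); sb <- segFromMask(e2)
  dense <- shapeTermDense(sa, sb)
  expect_equal(shapeTerm(sa, sb, linkParams()), dense, tolerance = 0.05)
  expect_gt(shapeTerm(sa, sb, linkParams()), 0.85)
})

test_that("shape term dominates position term (identity always searched)", {
  set.seed(11)
  for (rep in 1:10) {
    mA <- matrix(0L, 32, 32); mB <- matrix(0L, 32, 32)
    mA[sample(32, 1):32, sample(32, 1):32] <- 1L
    mB[sample(32, 1):32, sample(32, 1):32] <- 1L
    sa <- extractSegments(mA)[[1]]; sb <- extractSegments(mB)[[1]]
    expect_gte(shapeTerm(sa, sb, linkParams()), positionTerm(sa, sb))
  }
})

test_that("refined similarity follows its closed form and lambda monotonicity", {
  a <- segFromMask(squareMask(32, 32, 5, 5, 10))
  s <- segFromMask(squareMask(32, 32, 5, 10, 10))   # P = 1/3 vs a
  # identical pair: 1 at any lambda
  for (lam in c(0, 0.5, 2, 10))
    expect_equal(refinedSimilarity(a, a, linkParams(lambda = lam)), 1.0)
  # lambda = 0 reduces to P^2
  expect_equal(refinedSimilarity(a, s, linkParams(lambda = 0)), (1 / 3)^2)
  # P=0, S=1, lambda=2 -> 2/3
  b <- segFromMask(squareMask(48, 48, 30, 30, 10))
  a2 <- segFromMask(squareMask(48, 48, 5, 5, 10))
  expect_equal(refinedSimilarity(a2, b, linkParams(lambda = 2)), 2 / 3)

  # sign of d(c)/d(lambda) equals sign of S^2 - P^2
  P <- positionTerm(a, s); S <- shapeTerm(a, s, linkParams())
  expect_gt(S, P)
  lams <- c(0, 0.5, 1, 2, 5)
  vals <- vapply(lams, function(l)
    refinedSimilarity(a, s, linkParams(lambda = l)), numeric(1))
  expect_true(all(diff(vals) > 0))        # S > P: strictly increasing
  valsSame <- vapply(lams, function(l)
    refinedSimilarity(a, a, linkParams(lambda = l)), numeric(1))
  expect_equal(diff(valsSame), rep(0, length(lams) - 1L))  # S = P: constant
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("link parameters validate and round-trip through YAML and JSON", {
  expect_error(linkParams(lambda = -1), "lambda")
  expect_error(linkParams(Tl = 0.5, Th = 0.4), "Tl")
  expect_error(linkParams(Ts = 0.5, Th = 0.4), "Ts")
  p <- linkParams(Tl = 0.02, Th = 0.3, Ts = 0.04, lambda = 1.5,
                  skipEnabled = FALSE)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    writeLinkParams(p, f)
    q <- readLinkParams(f)
    expect_equal(q@Tl, 0.02); expect_equal(q@lambda, 1.5)
    expect_false(q@skipEnabled)
  }
  expect_equal(linkParams(preset = "synapse")@lambda, 2)
})
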