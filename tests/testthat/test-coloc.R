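# Image metrics: Manders coefficients, nuclear:cytoplasmic ratio, object
# colocalization percentage, linear unmixing.

test_that("Manders coefficients respect containment and disjointness", {
  A <- matrix(0, 30, 30); B <- matrix(0, 30, 30)
  B[5:25, 5:25] <- 10
  A[8:20, 8:20] <- 4          # A entirely inside B-positive pixels
  m <- mandersCoefficient(A, B, thresholdB = 1, thresholdA = 1)
  expect_equal(unname(m["M1"]), 1)
  expect_true(all(m >= 0 & m <= 1))

  A2 <- matrix(0, 30, 30); A2[27:30, 27:30] <- 5   # disjoint from B
  expect_equal(unname(mandersCoefficient(A2, B, 1, 1)["M1"]), 0)

  # constructed 90% mass split: 9 of 10 units of A inside B
  A3 <- matrix(0, 30, 30); A3[10:18, 10] <- 9 / 9; A3[1, 1] <- 1
  expect_equal(unname(mandersCoefficient(A3, B, 1, 1)["M1"]), 0.9)

  expect_error(mandersCoefficient(matrix(0, 3, 3), matrix(1, 3, 3), 0.5, 0.5),
               "no intensity")
  expect_error(mandersCoefficient(matrix(1, 3, 3), matrix(1, 4, 4)), "shapes")
})

test_that("Otsu default threshold separates a bimodal channel sensibly", {
  set.seed(6)
  B <- matrix(rnorm(400, 10, 1), 20, 20)
  B[5:15, 5:15] <- rnorm(121, 100, 5)
  A <- matrix(0, 20, 20); A[6:14, 6:14] <- 3
  m <- mandersCoefficient(A, B)
  expect_equal(unname(m["M1"]), 1)
})

test_that("nuclear:cytoplasmic ratio is a gain-invariant mean ratio", {
  img <- matrix(100, 12, 12)
  nuc <- matrix(FALSE, 12, 12); cyt <- matrix(FALSE, 12, 12)
  nuc[2:4, 2:4] <- TRUE; cyt[7:11, 7:11] <- TRUE
  expect_equal(ncRatio(img, nuc, cyt), 1)
  img[nuc] <- 280
  expect_equal(ncRatio(img, nuc, cyt), 2.8)
  expect_equal(ncRatio(img * 17, nuc, cyt), 2.8)
  expect_error(ncRatio(img, nuc, matrix(FALSE, 12, 12)), "empty")
  expect_error(ncRatio(img, nuc, nuc), "disjoint")
})

test_that("object colocalization percentage counts overlapping B objects", {
  oA <- matrix(0L, 25, 25); oB <- matrix(0L, 25, 25)
  for (i in 0:4) oB[1 + 5 * i, 1:4] <- i + 1L
  expect_error(percentColocalized(oA, oB * 0L), "no objects")
  expect_equal(percentColocalized(oB, oB), 100)
  expect_equal(percentColocalized(oA, oB), 0)

  oA[1, 1:4] <- 1L            # exactly 1 of 5 objects covered
  expect_equal(percentColocalized(oA, oB), 20)

  # half-area rule: an object only 25% covered does not count ...
  oA2 <- matrix(0L, 25, 25); oA2[1, 1] <- 1L
  expect_equal(percentColocalized(oA2, oB, "half_area"), 0)
  # ... but any-pixel overlap does
  expect_equal(percentColocalized(oA2, oB, "any_pixel"), 20)
})

test_that("linear unmixing is exact on noiseless stacks and non-negative", {
  sp <- SpectraMatrix(rbind(c(5, 3, 1, 0, 0), c(0, 1, 2, 5, 3),
                            c(1, 1, 1, 1, 1)))
  set.seed(14)
  ab <- array(runif(8 * 8 * 3) * 10, dim = c(8, 8, 3))
  st <- simLambdaStack(sp, ab)
  um <- linearUnmix(st, sp)
  expect_equal(um$abundance, ab, tolerance = 1e-7)
  expect_lt(max(um$residual), 1e-9)
  expect_true(all(um$abundance >= 0))

  # single-fluorophore stack: other abundances vanish
  ab1 <- ab; ab1[, , 2:3] <- 0
  um1 <- linearUnmix(simLambdaStack(sp, ab1), sp)
  expect_lt(max(um1$abundance[, , 2:3]), 1e-9)

  # unconstrained solve agrees when spectra are orthogonal
  spO <- SpectraMatrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 3)))
  abO <- array(runif(4 * 4 * 2), dim = c(4, 4, 2))
  stO <- simLambdaStack(spO, abO)
  expect_equal(linearUnmix(stO, spO, nonneg = TRUE)$abundance,
               linearUnmix(stO, spO, nonneg = FALSE)$abundance,
               tolerance = 1e-8)

  rankDef <- SpectraMatrix(rbind(c(1, 2, 3, 4, 0), c(2, 4, 6, 8, 0)))
  expect_error(linearUnmix(st, rankDef), "rank deficient")
})

test_that("metrics survive a common multiplicative gain", {
  set.seed(4)
  A <- matrix(runif(100), 10, 10); B <- matrix(runif(100), 10, 10)
  m1 <- mandersCoefficient(A, B, thresholdB = 0.5, thresholdA = 0.5)
  m2 <- mandersCoefficient(A * 3, B * 3, thresholdB = 1.5, thresholdA = 1.5)
  expect_equal(m1, m2)
})

test_that("trace and image containers round-trip through files", {
  tr <- simOscillatoryTrace(seed = 2, duration = 48)
  p <- tempfile(fileext = ".csv")
  writeTraceTable(tr, p)
  back <- readTraceTable(p)
  expect_equal(traceValues(back), traceValues(tr), tolerance = 1e-9)

  sp <- SpectraMatrix(rbind(c(2, 1, 0), c(0, 1, 2)))
  ab <- array(runif(6 * 6 * 2), dim = c(6, 6, 2))
  st <- simLambdaStack(sp, ab)
  tp <- tempfile(fileext = ".tif")
  scale <- writeLambdaStack(st, tp)
  back2 <- readLambdaStack(tp)
  expect_equal(back2@data * scale, st@data, tolerance = 1e-5)
})
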