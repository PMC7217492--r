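# Rhythmicity: spectra, autocorrelation, classification, cosinor fits,
# circadian-time mapping, rasters.

test_that("power spectrum finds the dominant period on clean signals", {
  t <- seq(0, 120, by = 0.5)
  ps <- powerSpectrum(FluorTrace(t, sin(2 * pi * t / 24)))
  expect_equal(ps$dominantPeriod, 24, tolerance = 0.6)
  expect_true(all(ps$power >= 0))

  # mixture: strongest component wins, matching the exhaustive DFT oracle
  mix <- sin(2 * pi * t / 24) + 0.3 * sin(2 * pi * t / 8)
  psMix <- powerSpectrum(FluorTrace(t, mix))
  expect_equal(psMix$dominantPeriod, 24, tolerance = 0.6)
  expect_equal(oracleDominantPeriod(mix, 0.5), 24, tolerance = 0.6)

  expect_error(powerSpectrum(FluorTrace(c(0, 1, 3, 7), rnorm(4))), "uniform")
})

test_that("white-noise dominant periods spread across the grid", {
  set.seed(77)
  doms <- replicate(100, {
    v <- rnorm(120)
    powerSpectrum(FluorTrace(seq(0, 59.5, 0.5), v), detrend = "mean")$dominantPeriod
  })
  # no quarter of the frequency grid hoards more than 3x its expected share
  f <- 1 / doms
  qs <- cut(f, breaks = seq(0, 1, length.out = 5), include.lowest = TRUE)
  expect_lt(max(table(qs)), 3 * 100 / 4)
})

test_that("autocorrelation is negative at half period and positive at one", {
  t <- seq(0, 120, by = 0.5)
  ac <- traceAutocorrelation(FluorTrace(t, sin(2 * pi * t / 24)), c(0, 12, 24))
  expect_equal(unname(ac["0h"]), 1)
  expect_lt(unname(ac["12h"]), 0)
  expect_gt(unname(ac["24h"]), 0)

  set.seed(13)
  n <- 500
  acn <- traceAutocorrelation(FluorTrace(seq_len(n), rnorm(n)),
                              lags = 1:80, demean = TRUE)
  expect_gte(mean(abs(acn[-1]) <= 3 / sqrt(n)), 0.99)
  expect_error(traceAutocorrelation(FluorTrace(1:10, rnorm(10)), lags = 50),
               "lag beyond")
})

test_that("single-track classification bins dominant periods correctly", {
  t <- seq(0, 120, by = 0.5)
  circ <- classifyTrack(FluorTrace(t, 100 + 5 * sin(2 * pi * t / 24)))
  expect_equal(circ$label, "circadian")
  ult <- classifyTrack(FluorTrace(t, 100 + 5 * sin(2 * pi * t / 8)))
  expect_equal(ult$label, "ultradian")
  expect_error(classifyTrack(FluorTrace(seq(0, 40, 0.5),
                                        rnorm(81) + 100)), "too short")
})

test_that("classification is invariant to affine intensity transforms", {
  co <- simCellCohort(5, 3, 5, seed = 17)
  for (i in seq_len(nrow(co))) {
    tr <- getTrace(co, i)
    shifted <- FluorTrace(traceTimes(tr), 3.7 * traceValues(tr) + 250)
    expect_identical(classifyTrack(tr)$label, classifyTrack(shifted)$label)
  }
})

test_that("cohort classification recovers the simulated composition", {
  co <- simCellCohort(45, 10, 45, seed = 7)
  cl <- classifyCohort(co)
  expect_equal(sum(cl$counts), 100)
  agree <- mean(cl$calls$label == cohortTruth(co)$label)
  expect_gte(agree, 0.9)

  single <- classifyCohort(simCellCohort(1, 0, 0, seed = 2))
  expect_equal(unname(single$counts),
               c(1, 0, 0))
})

test_that("damped-cosine fits round-trip and quantify robustness", {
  t <- seq(0, 120, by = 0.5)
  truth <- list(mesor = 100, A = 6, d = 0.01, phase = 5, P = 25.64)
  y <- truth$mesor + truth$A * exp(-truth$d * t) *
    cos(2 * pi * (t - truth$phase) / truth$P)
  fit <- fitDampedCosine(FluorTrace(t, y))
  expect_equal(cosinorPeriod(fit), truth$P, tolerance = 1e-4)
  expect_equal(fit@amplitude, truth$A, tolerance = 1e-4)
  expect_equal(cosinorPhase(fit), truth$phase, tolerance = 1e-3)
  expect_equal(fit@damping, truth$d, tolerance = 1e-3)
  expect_lt(fit@rss, 1e-12 * sum((y - mean(y))^2))
  expect_lt(relativeAmplitudeError(fit), 1e-6)

  # noisy cartilage-like record: period recovered within its uncertainty
  noisy <- simOscillatoryTrace(100, 0.0664, period = 25.64, phase = 5,
                               noiseSD = 0.01, duration = 120, seed = 3)
  nf <- fitDampedCosine(noisy)
  expect_equal(cosinorPeriod(nf), 25.64,
               tolerance = max(3 * nf@se[["P"]], 0.2) / 25.64)
  expect_gt(relativeAmplitudeError(nf), 0)
})

test_that("circadian-time mapping follows the PER2-anchored convention", {
  expect_equal(phaseToCT(10, 10, 24), 12)
  expect_equal(phaseToCT(22, 10, 24), 0)          # antiphase wraps to CT0
  expect_equal(phaseToCT(19.9, 12, 24), 19.9)     # 7.9 h lag -> CT19.9
  # periodicity: one full period added to the lag changes nothing
  for (dlt in c(0, 3.2, 11.7)) {
    expect_equal(phaseToCT(dlt, 0, 24.5), phaseToCT(dlt + 24.5, 0, 24.5))
  }
  expect_error(phaseToCT(1, 0, period = 0), "period")
})

test_that("raster matrices are normalized and phase-ordered", {
  co <- simCellCohort(8, 0, 0, noiseSD = 0.002, seed = 19)
  rm <- rasterMatrix(co, sortBy = "phase")
  expect_true(all(rm >= 0 & rm <= 1))
  expect_false(is.unsorted(attr(rm, "phase")))

  one <- rasterMatrix(simCellCohort(1, 0, 0, seed = 4), sortBy = "argmax")
  expect_equal(nrow(one), 1)
  expect_equal(range(one), c(0, 1))

  # synchronized cohort (shared phase): the population mean keeps the period
  set.seed(23)
  tt <- seq(0, 120, by = 0.5)
  mat <- t(replicate(12, traceValues(
    simOscillatoryTrace(100, 0.05, period = 24, phase = 6, noiseSD = 0.02,
                        duration = 120))))
  sync <- TraceCohort(mat, tt)
  avg <- colMeans(cohortIntensity(sync))
  ps <- powerSpectrum(FluorTrace(cohortTimes(sync), avg))
  expect_equal(ps$dominantPeriod, 24, tolerance = 1)
})
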