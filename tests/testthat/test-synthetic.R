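# Generators: closed-form correctness, determinism, and round-trip recovery.

test_that("oscillatory generator obeys its closed form and amplitude spec", {
  tr <- simOscillatoryTrace(baseline = 100, amplitudeFrac = 0.046,
                            period = 24, phase = 6, noiseSD = 0,
                            duration = 72)
  expect_equal(traceValues(tr),
               oscillatoryModel(traceTimes(tr), 100, 0.046, 24, phase = 6),
               tolerance = 1e-9)
  # peak sits amplitudeFrac * baseline above baseline at t = phase
  expect_equal(max(traceValues(tr)) - 100, 4.6, tolerance = 1e-9)
  expect_equal(traceValues(tr)[traceTimes(tr) == 6], 104.6, tolerance = 1e-9)

  flat <- simOscillatoryTrace(100, amplitudeFrac = 0, noiseSD = 0,
                              driftSlope = 0, duration = 48)
  expect_true(all(abs(traceValues(flat) - 100) < 1e-12))

  expect_error(simOscillatoryTrace(baseline = -1), "baseline")
  expect_error(simOscillatoryTrace(period = 0), "period")
})

test_that("trace noise matches an independent Monte-Carlo draw of the model", {
  tr <- simOscillatoryTrace(100, 0.05, noiseSD = 0.01, duration = 400,
                            samplingInterval = 0.5, seed = 42)
  resid <- traceValues(tr) -
    oscillatoryModel(traceTimes(tr), 100, 0.05, 24)
  set.seed(976)   # fresh, independent draw of the same noise model
  fresh <- rnorm(length(resid), sd = 0.01 * 100)
  expect_equal(var(resid), var(fresh), tolerance = 0.15)
  expect_equal(sd(resid), 1, tolerance = 0.1)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(simOscillatoryTrace(seed = 7), simOscillatoryTrace(seed = 7))
  expect_identical(
    cohortIntensity(simCellCohort(3, 2, 3, seed = 7)),
    cohortIntensity(simCellCohort(3, 2, 3, seed = 7)))
  expect_identical(simFcsCurve(N = 2, tauD = 1e-3, noiseSD = 0.01, seed = 7),
                   simFcsCurve(N = 2, tauD = 1e-3, noiseSD = 0.01, seed = 7))
  expect_identical(
    simActivityRecord("noise", days = 3, seed = 7)@counts,
    simActivityRecord("noise", days = 3, seed = 7)@counts)
})

test_that("cohort generator produces the requested composition and truth", {
  co <- simCellCohort(45, 10, 45, seed = 3)
  expect_equal(nrow(co), 100)
  truth <- cohortTruth(co)
  expect_equal(sum(truth$label == "circadian"), 45)
  expect_equal(sum(truth$label == "ultradian"), 10)
  expect_equal(sum(truth$label == "arrhythmic"), 45)
  per <- truth$period[truth$label == "circadian"]
  expect_true(all(per >= 15 & per <= 30))
  expect_true(all(truth$period[truth$label == "ultradian"] < 15))

  one <- simCellCohort(1, 0, 0, noiseSD = 0, dampingRate = 0,
                       driftSlope = 0, seed = 5)
  v <- cohortIntensity(one)[1, ]
  tt <- cohortTimes(one)
  expect_equal(v, oscillatoryModel(tt, 100, 0.05, cohortTruth(one)$period[1],
                                   cohortTruth(one)$phase[1]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(simCellCohort(0, 0, 0), "empty")
})

test_that("arrhythmic-only cohort has no circadian-band spectral dominance", {
  co <- simCellCohort(0, 0, 30, seed = 9)
  dt <- diff(cohortTimes(co))[1]
  doms <- apply(cohortIntensity(co), 1, oracleDominantPeriod, dt = dt)
  # exhaustive DFT oracle: random walks are dominated by long-period power
  expect_gte(mean(doms > 30), 0.85)
})

test_that("decay course generator matches the one-phase formula exactly", {
  tr <- simDecayCourse(1, 0, k = log(2), samplingInterval = 0.5, duration = 4)
  expect_equal(traceValues(tr)[traceTimes(tr) == 1], 0.5, tolerance = 1e-12)
  tr2 <- simDecayCourse(1, 0.1, k = 0.0866, samplingInterval = 0.1,
                        duration = 20)
  expect_equal(traceValues(tr2)[1], 1.0, tolerance = 1e-12)
  expect_equal(traceValues(tr2),
               (1 - 0.1) * exp(-0.0866 * traceTimes(tr2)) + 0.1,
               tolerance = 1e-12)
  # round-trip through the fitter
  fit <- fitOnePhaseDecay(tr2)
  expect_equal(decayRate(fit), 0.0866, tolerance = 1e-6)
  expect_error(simDecayCourse(k = -1), "k must be")
})

test_that("FRAP generator: pre-bleach frames, closed form, immobile case", {
  cv <- simFrapCurve(floor = 0.5, ampFast = 0.10, ampSlow = 0,
                     kFast = 0.1733, noiseSD = 0)
  expect_equal(cv@nPrebleach, 10L)
  expect_true(all(cv@times[1:10] < 0))
  f <- normalizeFrap(cv)
  at4 <- traceValues(f)[abs(traceTimes(f) - 4) < 1e-9]
  expect_equal(at4, 0.5 + 0.10 * (1 - exp(-0.1733 * 4)), tolerance = 1e-9)
  expect_equal(at4, 0.55, tolerance = 1e-3)

  frozen <- simFrapCurve(floor = 0.4, ampFast = 0, ampSlow = 0, noiseSD = 0)
  nf <- normalizeFrap(frozen)
  expect_true(all(abs(traceValues(nf)[traceTimes(nf) >= 0] - 0.4) < 1e-12))
  expect_error(simFrapCurve(ampFast = 0.1, kFast = -1), "rates")
  expect_error(simFrapCurve(floor = 1.2), "floor")
})

test_that("FCS generator honours the model limits and refits exactly", {
  beam <- BeamGeometry(0.2, 5)
  cv <- simFcsCurve(N = 4, tauD = 1e-3, T = 0, beam = beam)
  expect_equal(cv@G[1] - 1, 1 / 4, tolerance = 2e-3)     # tau -> 0 amplitude
  expect_equal(cv@G[length(cv@G)], 1, tolerance = 1e-3)  # decorrelation
  fit <- fitFcs(cv, beam)
  expect_equal(particleNumber(fit), 4, tolerance = 1e-6)
  expect_equal(diffusionTime(fit), 1e-3, tolerance = 1e-6)
  expect_error(simFcsCurve(N = 2, tauD = 1e-3, T = 1.2), "T must be")
})

test_that("activity generator patterns behave as designed", {
  tmpl <- c(rep(0, 12), 5, 20, 60, 80, 90, 70, 50, 30, 20, 10, 5, 0)
  rec <- simActivityRecord("repeat_template", binMinutes = 60, days = 10,
                           template = tmpl)
  m <- matrix(rec@counts, ncol = 10)
  cors <- cor(m)[upper.tri(diag(10))]
  expect_true(all(cors == 1))

  # law of large numbers: hourly means approach the grand mean as days grow
  spread <- vapply(c(20, 200), function(d) {
    r <- simActivityRecord("noise", binMinutes = 60, days = d, noiseSD = 10,
                           seed = 11)
    prof <- rowMeans(matrix(r@counts, nrow = 24))
    max(abs(prof - mean(r@counts)))
  }, numeric(1))
  expect_lt(spread[2], spread[1])

  fine <- simActivityRecord("sine", binMinutes = 6, days = 2)
  expect_equal(length(fine@counts), 2 * 24 * 10)
  expect_error(simActivityRecord("sine", binMinutes = 7, days = 2), "divide")
})

test_that("lambda-stack generator mixes spectra as stated", {
  sp <- SpectraMatrix(rbind(venus = c(0, 1, 3, 1), mem = c(2, 1, 0, 0)),
                      wavelengths = c(520, 560, 600, 640))
  ab <- array(0, dim = c(4, 4, 2)); ab[, , 1] <- 1
  st <- simLambdaStack(sp, ab)
  for (k in 1:4)
    expect_true(all(abs(st@data[, , k] - sp@spectra["venus", k]) < 1e-12))

  # orthogonal spectra: unmixing recovers the maps exactly (noiseless)
  spO <- SpectraMatrix(rbind(a = c(1, 0, 0, 0.5), b = c(0, 2, 1, 0)))
  set.seed(2)
  abO <- array(runif(4 * 4 * 2), dim = c(4, 4, 2))
  um <- linearUnmix(simLambdaStack(spO, abO), spO)
  expect_equal(um$abundance, abO, tolerance = 1e-9)

  # three-component stack emulating reporter/membrane/autofluorescence
  sp3 <- SpectraMatrix(rbind(c(1, 4, 2, 0, 0), c(0, 0, 1, 4, 2),
                             c(2, 2, 2, 2, 2)))
  ab3 <- array(runif(3 * 3 * 3), dim = c(3, 3, 3))
  expect_equal(dim(simLambdaStack(sp3, ab3)@data), c(3, 3, 5))
  expect_error(simLambdaStack(sp3, ab3[, , 1:2]), "fluorophores")
})

test_that("nuclear masks hit their target volume within one voxel", {
  vox <- c(0.2, 0.2, 0.5)
  for (target in c(306, 147)) {
    mk <- simNuclearMask(target, voxelDims = vox)
    expect_lt(abs(nuclearVolume(mk) - target), prod(vox) + 1e-9)
  }
  # analytic sphere check: radius 3.287 um -> 148.9 fL
  mk <- simNuclearMask(4 / 3 * pi * 3.287^3, voxelDims = vox)
  expect_equal(nuclearVolume(mk), 148.9, tolerance = 0.005)
  one <- simNuclearMask(0.005, voxelDims = c(0.1, 0.1, 0.5))
  expect_equal(sum(one), 1)
  expect_equal(nuclearVolume(one), 0.005, tolerance = 1e-12)
  expect_error(simNuclearMask(0.001, voxelDims = vox), "voxel larger")
})
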