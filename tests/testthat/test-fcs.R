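# FCS: model limits, independent-formula agreement, fitting, and conversion
# to absolute quantities.

test_that("the correlation model honours its analytic limits", {
  beam <- BeamGeometry(0.2, 5)
  # amplitude limit: G - 1 -> 1/N as tau -> 0 with no triplet
  expect_equal(fcsModel(1e-12, N = 2, tauD = 1e-3, T = 0, beam = beam) - 1,
               0.5, tolerance = 1e-8)
  # decorrelation: G -> 1 for tau >> tauD
  expect_equal(fcsModel(1e4, N = 2, tauD = 1e-3, T = 0, beam = beam), 1,
               tolerance = 1e-3)
  # at tau = tauD with an effectively infinite structure parameter,
  # G - 1 = 1/(2N)
  tall <- BeamGeometry(0.2, 1e9)
  expect_equal(fcsModel(1e-3, N = 3, tauD = 1e-3, T = 0, beam = tall) - 1,
               1 / 6, tolerance = 1e-9)
  # G is strictly decreasing in lag for T = 0
  lags <- exp(seq(log(1e-6), log(10), length.out = 300))
  expect_true(all(diff(fcsModel(lags, 5, 2e-3, 0, beam = beam)) < 0))
  expect_error(fcsModel(1e-3, N = 1, tauD = 1e-3, T = 1.1), "T must be")
})

test_that("model values match an independent formula evaluation", {
  beam <- BeamGeometry(0.23, 4.5)
  lags <- exp(seq(log(1e-6), log(10), length.out = 100))
  mine <- fcsModel(lags, N = 2.7, tauD = 3.1e-3, T = 0.12, tauT = 4e-6,
                   beam = beam)
  theirs <- oracleFcsG(lags, 2.7, 3.1e-3, 0.12, 4e-6, 0.23, 4.5)
  expect_lt(max(abs(mine - theirs)), 1e-12)
})

test_that("run averaging shrinks noise like the square root of run count", {
  beam <- BeamGeometry()
  truth <- simFcsCurve(N = 3, tauD = 2e-3, T = 0.1, beam = beam)
  runs <- lapply(1:5, function(i)
    simFcsCurve(N = 3, tauD = 2e-3, T = 0.1, beam = beam, noiseSD = 0.05,
                seed = 100 + i))
  avg <- averageRuns(runs)
  expect_equal(avg@runCount, 5L)
  expect_identical(averageRuns(runs[[1]]), runs[[1]])
  devSingle <- sqrt(mean((runs[[1]]@G - truth@G)^2))
  devAvg <- sqrt(mean((avg@G - truth@G)^2))
  expect_equal(devAvg / devSingle, 1 / sqrt(5), tolerance = 0.35)
  shifted <- FcsCurve(truth@lags * 2, truth@G)
  expect_error(averageRuns(list(truth, shifted)), "lag grids")
})

test_that("fits recover all four parameters on noiseless curves", {
  beam <- BeamGeometry(0.2, 5)
  cv <- simFcsCurve(N = 1.845, tauD = 5e-3, T = 0.15, tauT = 5e-6,
                    beam = beam)
  fit <- fitFcs(cv, beam)
  expect_equal(particleNumber(fit), 1.845, tolerance = 1e-6)
  expect_equal(diffusionTime(fit), 5e-3, tolerance = 1e-6)
  expect_equal(fit@T, 0.15, tolerance = 1e-4)
  expect_equal(fit@tauT, 5e-6, tolerance = 1e-3)
  # invariant: D * tauD = omega0^2 / 4 exactly
  expect_equal(diffusionCoefficient(fit) * diffusionTime(fit),
               beam@omega0^2 / 4, tolerance = 1e-12)
  # concentration recovered to <= 0.1%
  expect_equal(concentrationNM(fit), fcsConcentration(1.845, beam),
               tolerance = 1e-3)

  noTrip <- fitFcs(simFcsCurve(N = 3, tauD = 2e-3, T = 0, beam = beam), beam)
  expect_lt(noTrip@T, 0.01)
})

test_that("the study operating point yields D ~ 3.5 um^2/s", {
  beam <- BeamGeometry(0.2, 5)
  cv <- simFcsCurve(N = 3, tauD = 2.857e-3, T = 0.15, tauT = 5e-6,
                    beam = beam, noiseSD = 0.01, seed = 1)
  fit <- fitFcs(cv, beam)
  expect_equal(diffusionCoefficient(fit), 3.5, tolerance = 0.1)
  expect_lt(max(abs(fit@residuals)), 0.05 * (max(cv@G) - 1))
})

test_that("concentration and copy-number arithmetic is exact", {
  expect_equal(fcsConcentration(1.845, beam = 0.300), 10.2, tolerance = 0.002)
  expect_equal(fcsConcentration(2, BeamGeometry(0.23, 5)) /
                 fcsConcentration(1, BeamGeometry(0.23, 5)), 2)
  expect_equal(effectiveVolume(BeamGeometry(0.23, 5)),
               pi^1.5 * 0.23^3 * 5, tolerance = 1e-12)
  expect_equal(effectiveVolume(BeamGeometry(0.23, 5)), 0.339, tolerance = 0.01)

  expect_equal(moleculesPerNucleus(10.2, 147), 902.96, tolerance = 1e-4)
  expect_equal(moleculesPerNucleus(1, 1), 0.602214076, tolerance = 1e-9)
  expect_equal(moleculesPerNucleus(10, 0), 0)
})

test_that("error propagation matches a first-order Monte-Carlo oracle", {
  expect_equal(as.numeric(propagateSD(3, 0, 5, 0)), 0)
  expect_equal(as.numeric(propagateSD(1, 0, 7, 0.3)), 0.3)
  expect_equal(attr(propagateSD(2, 0.1, 3, 0.2), "radicand"),
               2^2 * 0.2^2 + 3^2 * 0.1^2)

  set.seed(99)
  mA <- 10.2; sA <- 1.0; mB <- 147; sB <- 12
  a <- exp(rnorm(2e5, log(mA) - 0.5 * (sA / mA)^2, sA / mA))
  b <- exp(rnorm(2e5, log(mB) - 0.5 * (sB / mB)^2, sB / mB))
  expect_equal(as.numeric(propagateSD(mA, sA, mB, sB)), sd(a * b),
               tolerance = 0.1)
})

test_that("nuclear volume is a voxel sum, invariant to translation", {
  mk <- simNuclearMask(147)
  vol <- nuclearVolume(mk)
  shifted <- array(FALSE, dim = dim(mk) + 2L)
  shifted[-(1:2), -(1:2), -(1:2)] <- mk
  expect_equal(sum(shifted) * prod(attr(mk, "voxelDims")), vol)
  expect_error(nuclearVolume(array(FALSE, c(3, 3, 3)),
                             voxelDims = c(1, 1, 1)), "empty")
})
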