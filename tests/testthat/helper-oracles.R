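# Independent oracles used across tests. These deliberately avoid the package
# code paths they are checked against: the DFT oracle is an explicit
# trigonometric sum, the FCS oracle a literal transcription of the model
# formula, and the circular-mean oracle a from-scratch vector average.

# Dominant period by exhaustive scan of an explicitly summed DFT.
oracleDominantPeriod <- function(values, dt, detrend = TRUE) {
  n <- length(values)
  if (detrend) {
    t <- seq_len(n)
    values <- values - stats::fitted(stats::lm(values ~ t))
  } else {
    values <- values - mean(values)
  }
  ks <- seq_len(floor(n / 2))
  power <- vapply(ks, function(k) {
    w <- 2 * pi * k * (seq_len(n) - 1) / n
    sum(values * cos(w))^2 + sum(values * sin(w))^2
  }, numeric(1))
  n * dt / ks[which.max(power)]
}

# Literal one-component triplet diffusion autocorrelation.
oracleFcsG <- function(lag, N, tauD, Tf, tauT, omega0, S) {
  tripletTerm <- 1 + (Tf * exp(-lag / tauT)) / (1 - Tf)
  diffusionTerm <- 1 / (1 + lag / tauD) / sqrt(1 + lag / (S * S * tauD))
  1 + tripletTerm * diffusionTerm / N
}

# Circular mean of clock hours via unit vectors.
oracleCircularMean <- function(hours) {
  z <- exp(1i * 2 * pi * hours / 24)
  (Arg(mean(z)) * 24 / (2 * pi)) %% 24
}

# FLIP fixture: a bleached-cell nuclear trace with a programmed fractional
# loss, three unbleached neighbour controls sharing the acquisition
# bleaching, and a constant background offset.
makeFlipFixture <- function(loss, seed = 1, noiseSD = 1) {
  set.seed(seed)
  t <- c(-rev(seq_len(5)) * 3.73, seq(0, 3.73 * 150, by = 3.73))
  lossCurve <- ifelse(t < 0, 1, 1 - loss * (1 - exp(-t / 30)))
  acq <- exp(-5e-4 * (t - t[1]))
  bg <- 20
  nuclear <- FluorTrace(t, 500 * lossCurve * acq + bg +
                          rnorm(length(t), sd = noiseSD))
  controls <- lapply(1:3, function(i)
    FluorTrace(t, 500 * acq + bg + rnorm(length(t), sd = noiseSD)))
  list(nuclear = nuclear, controls = controls,
       background = FluorTrace(t, rep(bg, length(t))))
}

# qPCR course: target decaying at rate k (per minute) against two constant
# reference genes, expressed in Ct space (one cycle = factor 2).
makeQpcrCourse <- function(k, times = seq(0, 240, by = 30)) {
  rel <- exp(-k * times)
  rbind(
    data.frame(time = times, gene = "target", Ct = 20 - log2(rel)),
    data.frame(time = times, gene = "ref1", Ct = 18),
    data.frame(time = times, gene = "ref2", Ct = 22))
}
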