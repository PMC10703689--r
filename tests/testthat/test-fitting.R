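test_that("high-pass detrend rejects DC and preserves in-band signal", {
  # constant stream maps to (numerically) zero
  out <- detrendHighpass(rep(3.7, 4000), 5000)
  expect_lt(mean(abs(out)), 1e-9 * 3.7)
  # 1 Hz drift at 5 kHz sampling, 50 Hz cutoff: strongly attenuated.
  # Independent expectation: first-order Butterworth |H(1 Hz)| ~ 0.02 per
  # pass, squared by the forward-backward filter, so well below 1/50.
  t <- seq(0, 20, by = 1 / 5000)
  y1 <- detrendHighpass(sin(2 * pi * t), 5000)
  i <- 25000:75000                       # interior, away from edge transients
  amp <- function(v) sqrt(2) * sd(v)
  expect_lt(amp(y1[i]), 1 / 50)
  # 500 Hz (10x cutoff): amplitude preserved within 1%
  y500 <- detrendHighpass(sin(2 * pi * 500 * t), 5000)
  expect_gt(amp(y500[i]), 0.99)
  expect_error(detrendHighpass(rnorm(100), 80, cutoffHz = 50), "Nyquist")
})

test_that("single-Lorentzian fit recovers noiseless truth to 1e-6", {
  ax <- waterAxis()
  f <- fitLorentzian(makeSpectrum(ax, LorentzianPeaks(5.000, 0.459, 1.0)))
  expect_true(converged(f))
  expect_equal(shiftGHz(peaks(f)), 5.000, tolerance = 1e-6)
  expect_equal(fwhmGHz(peaks(f)), 0.459, tolerance = 1e-6)
  expect_equal(amplitude(peaks(f)), 1.0, tolerance = 1e-6)
  expect_lt(residualRms(f), 1e-8)
})

test_that("a flat or signal-free spectrum yields a non-converged flag", {
  ax <- waterAxis()
  f <- fitLorentzian(BrillouinSpectrum(ax, rep(0, 100)))
  expect_false(converged(f))
  # pure noise, no peak
  set.seed(8)
  fn <- fitLorentzian(BrillouinSpectrum(ax, rnorm(100, 0, 0.01)))
  expect_false(converged(fn))
  expect_error(fitLorentzian(BrillouinSpectrum(c(4, 5, 6), c(0, 1, 0))),
               "at least 5")
})

test_that("fitting is invariant under frequency-axis translation", {
  ax <- waterAxis()
  set.seed(14)
  for (i in 1:5) {
    y <- gainValues(makeSpectrum(ax, waterPeak(), snr = 38))
    delta <- runif(1, -2, 2)
    f0 <- fitLorentzian(BrillouinSpectrum(ax, y))
    f1 <- fitLorentzian(BrillouinSpectrum(ax + delta, y))
    expect_equal(shiftGHz(peaks(f1)), shiftGHz(peaks(f0)) + delta,
                 tolerance = 1e-8)
    expect_equal(fwhmGHz(peaks(f1)), fwhmGHz(peaks(f0)), tolerance = 1e-8)
  }
})

test_that("least-squares loss never exceeds the exhaustive grid oracle", {
  # 50-point spectra; oracle enumerates (shift, fwhm) at 0.01 GHz resolution
  # with the amplitude and baseline solved exactly per grid point
  ax <- makeFrequencyAxis(4, 6, 50)
  step <- diff(ax)[1]
  shifts <- seq(4, 6, by = 0.01)
  fwhms <- seq(2 * step, 2, by = 0.01)
  set.seed(23)
  for (i in 1:8) {
    y <- gainValues(makeSpectrum(ax, waterPeak(), snr = runif(1, 10, 60)))
    f <- fitLorentzian(BrillouinSpectrum(ax, y))
    pk <- peaks(f)
    model <- lorentzian(ax, pk) + baseline(f)
    ssrFit <- sum((y - model)^2)
    ssrGrid <- gridSearchLorentzian(ax, y, shifts, fwhms)$ssr
    expect_lte(ssrFit, ssrGrid + 1e-10)
  }
})

test_that("fitted shift scatter matches the brute-force ML oracle at SNR 38", {
  # oracle first: dense-grid maximum-likelihood (least-squares) search on the
  # same 300 noisy draws, then compare the scatter of the two estimators
  ax <- waterAxis()
  n <- 300
  set.seed(38)
  Y <- vapply(seq_len(n), function(i)
    gainValues(makeSpectrum(ax, waterPeak(), snr = 38)), numeric(100))
  oracleShift <- gridSearchShifts(ax, Y, shifts = seq(4.9, 5.1, by = 0.002),
                                  fwhms = seq(0.35, 0.57, by = 0.01))
  fitShift <- vapply(seq_len(n), function(i)
    shiftGHz(peaks(fitLorentzian(BrillouinSpectrum(ax, Y[, i])))), numeric(1))
  expect_equal(sd(fitShift), sd(oracleShift), tolerance = 0.2)
})

test_that("fitted shift precision scales inversely with SNR", {
  ax <- waterAxis()
  snrs <- c(10, 30, 100, 300)
  set.seed(55)
  sds <- vapply(snrs, function(sn) {
    sh <- replicate(60, shiftGHz(peaks(fitLorentzian(
      makeSpectrum(ax, waterPeak(), snr = sn)))))
    sd(sh)
  }, numeric(1))
  slope <- unname(coef(lm(log10(sds) ~ log10(snrs)))[2])
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("multi-Lorentzian fit recovers separated noiseless peaks", {
  ax <- makeFrequencyAxis(4, 7, 150)
  truth <- LorentzianPeaks(c(5.03, 5.80), c(0.46, 0.46), c(1.0, 0.8))
  f <- fitMultiLorentzian(makeSpectrum(ax, truth), 2)
  expect_true(converged(f))
  expect_false(isDegenerate(f))
  expect_equal(shiftGHz(peaks(f)), c(5.03, 5.80), tolerance = 1e-4)
  expect_equal(fwhmGHz(peaks(f)), c(0.46, 0.46), tolerance = 1e-4)
  expect_equal(amplitude(peaks(f)), c(1.0, 0.8), tolerance = 1e-4)
  expect_lt(residualRms(f), 1e-8)
  # peaks come back sorted by ascending shift
  expect_true(!is.unsorted(shiftGHz(peaks(f))))
  expect_error(fitMultiLorentzian(makeSpectrum(ax, truth), 4), "nPeaks")
  expect_error(fitMultiLorentzian(makeSpectrum(ax, truth), 1), "nPeaks")
})

test_that("coincident generated peaks raise the degeneracy flag", {
  ax <- makeFrequencyAxis(4, 6, 100)
  truth <- LorentzianPeaks(c(5.0, 5.0), c(0.459, 0.459), c(0.6, 0.6))
  f <- fitMultiLorentzian(makeSpectrum(ax, truth), 2)
  expect_true(isDegenerate(f))
})

test_that("brillouinGain is the amplitude to DC ratio", {
  f <- new("BrillouinFit", peaks = LorentzianPeaks(5, 0.4, 0.5), baseline = 0,
           stdErrors = NA_real_, residualRms = 0, converged = TRUE,
           degenerate = FALSE)
  expect_equal(brillouinGain(f, 100), 0.005)
  f2 <- new("BrillouinFit", peaks = LorentzianPeaks(5, 0.4, 1.0), baseline = 0,
            stdErrors = NA_real_, residualRms = 0, converged = TRUE,
            degenerate = FALSE)
  expect_equal(brillouinGain(f2, 100), 2 * brillouinGain(f, 100))
  expect_error(brillouinGain(f, 0), "dcLevel")
})

test_that("SNR estimation from an off-resonance window", {
  ax <- makeFrequencyAxis(4, 9, 250)
  s <- makeSpectrum(ax, waterPeak(), snr = 38, seed = 2)
  f <- fitLorentzian(s)
  # synthetic exact case: amplitude 10, alternating +/-0.5 "noise" floor in
  # the window (and no peak contribution there)
  vals <- rep(c(0.5, -0.5), length.out = 250)
  vals[ax < 7] <- lorentzian(ax[ax < 7], waterPeak()) * 10
  sKnown <- BrillouinSpectrum(ax, vals)
  fKnown <- new("BrillouinFit", peaks = LorentzianPeaks(5, 0.459, 10),
                baseline = 0, stdErrors = NA_real_, residualRms = 0,
                converged = TRUE, degenerate = FALSE)
  expect_equal(estimateSNR(sKnown, fKnown, c(7, 9)),
               10 / sd(vals[ax >= 7 & ax <= 9]))
  # a window with zero variance means unbounded SNR: distinct error state
  flat <- vals; flat[ax >= 7] <- 0
  expect_error(estimateSNR(BrillouinSpectrum(ax, flat), fKnown, c(7, 9)),
               class = "sbsUnboundedSNR")
  # window overlapping the peak is rejected
  expect_error(estimateSNR(s, f, c(5.5, 7)), "overlaps")
  expect_error(estimateSNR(s, f, c(8.95, 9)), "fewer than 5")
  # Monte-Carlo: estimate within 15% of the requested SNR over 100 draws
  set.seed(13)
  est <- replicate(100, {
    si <- makeSpectrum(ax, waterPeak(), snr = 38)
    estimateSNR(si, fitLorentzian(si), c(7, 9))
  })
  expect_equal(mean(est), 38, tolerance = 0.15)
})
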