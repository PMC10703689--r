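test_that("frequency-axis calibration subtracts the differential frequency", {
  ax <- makeFrequencyAxis(4, 6, 10)
  expect_identical(calibrateFrequencyAxis(ax, 5.00, 5.00), ax)
  expect_equal(calibrateFrequencyAxis(ax, 5.03, 5.00), ax - 0.03)
  # roundtrip: a fast-scan spectrum recorded on an offset axis, once
  # calibrated, fits back to the slow-scan truth
  off <- 0.03
  fastAxis <- makeFrequencyAxis(4, 6, 100) + off
  y <- lorentzian(fastAxis - off, waterPeak())   # instrument sees the offset
  f <- fitLorentzian(BrillouinSpectrum(
    calibrateFrequencyAxis(fastAxis, 5.00 + off, 5.00), y))
  expect_equal(shiftGHz(peaks(f)), 5.00, tolerance = 1e-8)
})

test_that("spectral resolution subtraction matches the instrument bookkeeping", {
  expect_equal(round(spectralResolution(459.2, 308)), 151)
  expect_equal(round(spectralResolution(410, 308)), 102)
  expect_equal(round(spectralResolution(459.2, 410)), 49)
  expect_identical(spectralResolution(308, 308), 0)
  expect_error(spectralResolution(300, 308), "unphysical")
  # exact additivity: res(a,b) + res(b,c) = res(a,c)
  expect_identical(spectralResolution(459.2, 410) + spectralResolution(410, 308),
                   spectralResolution(459.2, 308))
})

test_that("precision curve reports per-time scatter of the fits", {
  ax <- waterAxis()
  # identical repeats (same seed): zero scatter
  same <- list("20" = replicate(3, makeSpectrum(ax, waterPeak(), snr = 38,
                                                seed = 1), simplify = FALSE))
  pc0 <- precisionCurve(same)
  expect_identical(pc0@shiftSdGHz, 0)
  # 300 repeats: scatter within 20% of the numeric Cramer-Rao-style bound
  ser <- makeSpectrumSeries(ax, waterPeak(), nRepeats = 300,
                            integrationTimesMs = 20, seed = 46)
  pc <- precisionCurve(ser)
  bound <- crlbShiftSd(ax, waterPeak(), 1 / 38)
  expect_equal(pc@shiftSdGHz, bound, tolerance = 0.2)
  # doubling the noise doubles the scatter (within sampling error)
  serHalf <- makeSpectrumSeries(ax, waterPeak(), nRepeats = 300,
                                integrationTimesMs = 20, baseSnr = 19,
                                seed = 46)
  pcHalf <- precisionCurve(serHalf)
  expect_equal(pcHalf@shiftSdGHz / pc@shiftSdGHz, 2, tolerance = 0.15)
  expect_error(precisionCurve(list("20" = same[["20"]][1])), "2 repeats")
})

test_that("precision slope identifies shot-noise and constant-noise scaling", {
  times <- c(5, 10, 20, 40, 80)
  exact <- new("PrecisionCurve", timesMs = times,
               shiftSdGHz = 0.01 * times^(-0.5),
               widthSdGHz = 0.04 * times^(-0.5), nRepeats = rep(300L, 5))
  expect_equal(precisionSlope(exact), -0.5, tolerance = 1e-12)
  expect_equal(precisionSlope(exact, "linewidth"), -0.5, tolerance = 1e-12)
  flat <- new("PrecisionCurve", timesMs = times,
              shiftSdGHz = rep(0.01, 5), widthSdGHz = rep(0.04, 5),
              nRepeats = rep(300L, 5))
  expect_equal(precisionSlope(flat), 0, tolerance = 1e-12)
  zero <- new("PrecisionCurve", timesMs = times,
              shiftSdGHz = c(0, rep(0.01, 4)), widthSdGHz = rep(0.01, 5),
              nRepeats = rep(300L, 5))
  expect_error(precisionSlope(zero), "zero standard deviation")
})

test_that("erf edge fits recover the point-spread FWHM", {
  x <- seq(-5, 5, by = 0.25)
  r <- fitEdgeErf(x, 0.5 + 0.5 * erfRef(x / sqrt(2)))   # sigma = 1
  expect_true(r$converged)
  expect_equal(r$fwhmUm, 2.3548, tolerance = 1e-4)
  # generator FWHMs matching the instrument's lateral and axial resolutions
  for (fw in c(0.55, 0.57, 2.58)) {
    sg <- fw / (2 * sqrt(2 * log(2)))
    xx <- seq(-3 * fw, 3 * fw, length.out = 120)   # 20 samples per FWHM
    yy <- 1 - 0.5 * (1 + erfRef(xx / (sg * sqrt(2))))  # falling edge
    rr <- fitEdgeErf(xx, yy)
    expect_true(rr$converged)
    expect_equal(rr$fwhmUm, fw, tolerance = 0.01)
  }
  # a hard step collapses to (at most) one position step
  xs <- seq(-2, 2, by = 0.1)
  rs <- fitEdgeErf(xs, as.numeric(xs > 0))
  expect_true(rs$converged)
  expect_lt(rs$fwhmUm, 0.1)
  # no dominant monotone trend: flagged, not fitted
  set.seed(2)
  rnd <- fitEdgeErf(xs, rnorm(length(xs)))
  expect_false(rnd$converged)
  expect_error(fitEdgeErf(c(1, 2, 2, 3, 4), rep(0, 5)), "monotone")
})

test_that("edge width recovered from an amplitude map across the bead edge", {
  # smooth-edge bead: amplitude of the 5.12 GHz component falls from the
  # agarose plateau to zero across the bead with a known erf profile
  g <- ScanGeometry(nx = 41, ny = 1, nz = 1, nFreq = 60, stepX = 0.25,
                    serpentine = FALSE, zFlip = FALSE)
  ax <- makeFrequencyAxis(3.5, 6.5, 60)
  xUm <- (seq_len(41) - 21) * 0.25
  fwTrue <- 0.57
  sg <- fwTrue / (2 * sqrt(2 * log(2)))
  wAg <- 0.5 * (1 + erfRef(xUm / (sg * sqrt(2))))   # agarose weight
  A <- vapply(seq_len(41), function(i)
    lorentzian(ax, LorentzianPeaks(5.12, 0.40, 1)) * wAg[i] +
    lorentzian(ax, LorentzianPeaks(4.07, 0.35, 1)) * (1 - wAg[i]),
    numeric(60))
  cube <- SpectralCube(A, ax, g)
  fits <- fitCube(cube, nPeaks = 2)
  ampAt512 <- vapply(fits$fits, function(f) {
    pk <- peaks(f)
    sel <- which.min(abs(shiftGHz(pk) - 5.12))
    if (abs(shiftGHz(pk)[sel] - 5.12) < 0.2) amplitude(pk)[sel] else 0
  }, numeric(1))
  r <- fitEdgeErf(xUm, ampAt512)
  expect_true(r$converged)
  expect_equal(r$fwhmUm, fwTrue, tolerance = 0.05)
})

test_that("scan-range study: wider ranges do not degrade fidelity", {
  srs <- scanRangeStudy(waterPeak(), c(2, 4), snr = 38, nRepeats = 300,
                        seed = 77)
  expect_lte(srs$shift_sd_ghz[2], 1.1 * srs$shift_sd_ghz[1])
  # seeded reproducibility
  srs2 <- scanRangeStudy(waterPeak(), c(2, 4), snr = 38, nRepeats = 300,
                         seed = 77)
  expect_identical(srs, srs2)
  # infinite SNR: zero bias at every range
  srs0 <- scanRangeStudy(waterPeak(), c(2, 3), snr = Inf, nRepeats = 3,
                         seed = 1)
  expect_lt(max(abs(srs0$shift_bias_ghz)), 1e-8)
  expect_lt(max(abs(srs0$fwhm_bias_ghz)), 1e-8)
  expect_error(scanRangeStudy(waterPeak(), c(0.5, 2)), "2 FWHM")
})
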