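mkFit <- function(peaks) new("BrillouinFit", peaks = peaks, baseline = 0,
                             stdErrors = NA_real_, residualRms = 0,
                             converged = TRUE, degenerate = FALSE)

test_that("derivative zero-crossing counts follow unimodal/bimodal calculus", {
  one <- mkFit(LorentzianPeaks(5, 0.459, 1))
  expect_identical(countDerivativeZeroCrossings(one, 0, c(4, 6)), 1L)
  # two equal peaks separated by 4 FWHM: max, min, max of the sum
  two <- mkFit(LorentzianPeaks(c(5, 5 + 4 * 0.4), c(0.4, 0.4), c(1, 1)))
  expect_identical(countDerivativeZeroCrossings(two, 0, c(4, 8)), 3L)
  nc <- new("BrillouinFit", peaks = LorentzianPeaks(5, 0.4, 1), baseline = 0,
            stdErrors = NA_real_, residualRms = 0, converged = FALSE,
            degenerate = FALSE)
  expect_error(countDerivativeZeroCrossings(nc, 0, c(4, 6)), "converged")
})

test_that("a merged shoulder is invisible at zero offset but found by the sweep", {
  # amplitudes 1.0 and 0.35, separation 0.7 FWHM: a shoulder, not two maxima
  sh <- mkFit(LorentzianPeaks(c(5, 5 + 0.7 * 0.4), c(0.4, 0.4), c(1, 0.35)))
  expect_identical(countDerivativeZeroCrossings(sh, 0, c(4, 6.5)), 1L)
  offs <- seq(0.05, 0.5, by = 0.05)
  counts <- vapply(offs, function(o)
    countDerivativeZeroCrossings(sh, o, c(4, 6.5)), integer(1))
  expect_true(any(counts > 2L))
})

test_that("analytic crossing counts agree with finite-difference brute force", {
  set.seed(71)
  for (i in 1:100) {
    pk <- LorentzianPeaks(
      shiftGHz = c(5, 5 + runif(1, 0.2, 2.5)),
      fwhmGHz = runif(2, 0.2, 0.8),
      amplitude = runif(2, 0.2, 1))
    off <- sample(c(0, -0.25, 0.25), 1)
    got <- countDerivativeZeroCrossings(mkFit(pk), off, c(3.5, 8.5),
                                        nGrid = 1e4L)
    expect_identical(got, fdZeroCrossings(pk, off, c(3.5, 8.5), nGrid = 1e4L))
  }
})

test_that("noiseless single and double peaks classify as such", {
  ax <- makeFrequencyAxis(4, 6, 100)
  cl1 <- classifySpectrum(makeSpectrum(ax, waterPeak()))
  expect_identical(classificationLabel(cl1), "single")
  expect_identical(multiPeakMetric(cl1), 0)
  expect_false(cl1@fitFailed)

  ax2 <- makeFrequencyAxis(4, 7, 150)
  cl2 <- classifySpectrum(makeSpectrum(ax2,
    LorentzianPeaks(c(5.03, 5.80), c(0.46, 0.46), c(1, 0.8))))
  expect_identical(classificationLabel(cl2), "multi")
  expect_gt(multiPeakMetric(cl2), 0)
  expect_gte(cl2@nExtremaZeroOffset, 3L)
})

test_that("classification survives amplitude rescaling", {
  ax <- makeFrequencyAxis(4, 7, 150)
  set.seed(99)
  for (i in 1:5) {
    y <- gainValues(makeSpectrum(ax,
      LorentzianPeaks(c(5.03, 5.80), c(0.46, 0.46), c(1, 0.8)), snr = 38))
    for (scale in c(1e-3, 1, 250)) {
      cl <- classifySpectrum(BrillouinSpectrum(ax, y * scale))
      expect_identical(classificationLabel(cl), "multi")
    }
  }
  # and a rescaled single peak stays single
  y1 <- gainValues(makeSpectrum(makeFrequencyAxis(4, 6, 100), waterPeak(),
                                snr = 38, seed = 4))
  for (scale in c(1e-3, 250))
    expect_identical(
      classificationLabel(classifySpectrum(
        BrillouinSpectrum(makeFrequencyAxis(4, 6, 100), y1 * scale))),
      "single")
})

test_that("a failed fit classifies single with metric 0 and a warning flag", {
  ax <- makeFrequencyAxis(4, 6, 100)
  cl <- classifySpectrum(BrillouinSpectrum(ax, rep(0, 100)))
  expect_identical(classificationLabel(cl), "single")
  expect_identical(multiPeakMetric(cl), 0)
  expect_true(cl@fitFailed)
})

test_that("detection of equal doublets is reliable above a separation that shrinks with SNR", {
  ax <- makeFrequencyAxis(3.5, 8, 160)
  seps <- c(0.5, 0.75, 1.0, 1.5, 2.0)      # in units of FWHM (0.46 GHz)
  detRate <- function(sepF, snr, n = 25) {
    pk <- LorentzianPeaks(c(5, 5 + sepF * 0.46), c(0.46, 0.46), c(1, 1))
    hits <- replicate(n, classificationLabel(
      classifySpectrum(makeSpectrum(ax, pk, snr = snr))) == "multi")
    mean(hits)
  }
  set.seed(123)
  thresholdFor <- function(snr) {
    r <- vapply(seps, detRate, numeric(1), snr = snr)
    seps[which(r >= 0.99)[1]]
  }
  th <- vapply(c(30, 100, 300), thresholdFor, numeric(1))
  expect_true(all(is.finite(th)))          # a reliable separation exists
  expect_true(all(diff(th) <= 0))          # and it shrinks (or holds) with SNR
})

test_that("metric maps are zero on single-peak pixels and confined to overlaps", {
  g <- ScanGeometry(nx = 4, ny = 9, nz = 1, nFreq = 120)
  ax <- makeFrequencyAxis(4, 7, 120)
  # uniform water: all-zero metric map
  simW <- makeScanStream(makePhantom("water", g), g, ax)
  fw <- fitCube(reconstructScan(simW), nPeaks = 1, classify = TRUE)
  mapW <- multiPeakMetricMap(fw$classifications, g)
  expect_true(all(mapW == 0))
  # two-layer phantom: nonzero metric only inside the overlap stripe
  ph <- makePhantom("two_layer", g, overlapHalfWidth = 1)
  sim <- makeScanStream(ph, g, ax)
  fc <- fitCube(reconstructScan(sim), nPeaks = 1, classify = TRUE)
  m <- multiPeakMetricMap(fc$classifications, g)
  stripe <- ph@labels == "both"
  expect_true(all(m[stripe] > 0))
  expect_true(all(m[!stripe] == 0))
  # map values equal the per-pixel classification metrics
  mets <- vapply(fc$classifications, multiPeakMetric, numeric(1))
  expect_identical(as.vector(m), mets)
  # missing pixels are masked, not interpolated
  cls <- fc$classifications; cls[5] <- list(NULL)
  m2 <- multiPeakMetricMap(cls, g)
  expect_true(is.na(m2[5]))
})
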