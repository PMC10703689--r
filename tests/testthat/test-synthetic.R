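test_that("frequency axis is uniform, increasing and bounded", {
  ax <- makeFrequencyAxis(4, 6, 100)
  expect_length(ax, 100)
  expect_equal(range(ax), c(4, 6))
  expect_true(all(diff(ax) > 0))
  expect_equal(diff(range(diff(ax))), 0, tolerance = 1e-12)
  expect_error(makeFrequencyAxis(6, 4, 100), "startGHz")
  expect_error(makeFrequencyAxis(4, 6, 2), "nPoints")
})

test_that("makeSpectrum adds calibrated, reproducible Gaussian noise", {
  ax <- waterAxis()
  # infinite SNR: exactly the noiseless model
  s0 <- makeSpectrum(ax, waterPeak())
  expect_identical(gainValues(s0), lorentzian(ax, waterPeak()))
  # same seed twice: identical draw
  s1 <- makeSpectrum(ax, waterPeak(), snr = 38, seed = 5)
  s2 <- makeSpectrum(ax, waterPeak(), snr = 38, seed = 5)
  expect_identical(gainValues(s1), gainValues(s2))
  expect_false(identical(gainValues(makeSpectrum(ax, waterPeak(), snr = 38, seed = 6)),
                         gainValues(s1)))
  # empirical residual std over 1e4 points within 5% of amplitude/snr
  axBig <- makeFrequencyAxis(4, 6, 1e4)
  sBig <- makeSpectrum(axBig, waterPeak(), snr = 38, seed = 11)
  resid <- gainValues(sBig) - lorentzian(axBig, waterPeak())
  expect_equal(sd(resid), 1 / 38, tolerance = 0.05)
  expect_error(makeSpectrum(ax, waterPeak(), snr = -2), "snr")
})

test_that("makeSpectrum noise is homoscedastic across the axis", {
  axBig <- makeFrequencyAxis(4, 6, 4000)
  s <- makeSpectrum(axBig, waterPeak(), snr = 38, seed = 21)
  resid <- gainValues(s) - lorentzian(axBig, waterPeak())
  bins <- cut(seq_along(resid), 8)
  sds <- tapply(resid, bins, sd)
  # all per-bin std estimates consistent with the global value
  expect_true(all(abs(sds - 1 / 38) / (1 / 38) < 0.15))
})

test_that("spectrum series scales noise as integration time^(-1/2)", {
  ax <- waterAxis()
  ser <- makeSpectrumSeries(ax, waterPeak(), nRepeats = 50,
                            integrationTimesMs = c(5, 20, 80), seed = 31)
  model <- lorentzian(ax, waterPeak())
  sdAt <- vapply(ser, function(reps)
    sd(unlist(lapply(reps, function(s) gainValues(s) - model))), numeric(1))
  # t quadrupled -> noise std halved (shot-noise square-root law)
  expect_equal(sdAt[["5"]] / sdAt[["20"]], 2, tolerance = 0.05)
  expect_equal(sdAt[["20"]] / sdAt[["80"]], 2, tolerance = 0.05)
  # SNR 38 at the 20 ms reference time
  expect_equal(sdAt[["20"]], 1 / 38, tolerance = 0.05)
  # determinism and metadata
  ser2 <- makeSpectrumSeries(ax, waterPeak(), nRepeats = 50,
                             integrationTimesMs = c(5, 20, 80), seed = 31)
  expect_identical(gainValues(ser[["80"]][[50]]), gainValues(ser2[["80"]][[50]]))
  expect_equal(integrationTimeMs(ser[["5"]][[1]]), 5)
  expect_error(makeSpectrumSeries(ax, waterPeak(), integrationTimesMs = c(0, 5)),
               "times")
  expect_error(makeSpectrumSeries(ax, waterPeak(), nRepeats = 1), "nRepeats")
})

test_that("phantoms carry the documented material resonances", {
  g <- ScanGeometry(nx = 12, ny = 12, nz = 2, nFreq = 50)
  bead <- makePhantom("bead_in_agarose", g)
  shifts <- sort(vapply(bead@materials, function(p) shiftGHz(p)[1], numeric(1)))
  expect_equal(unname(shifts), c(4.07, 5.12))
  expect_setequal(unique(as.vector(bead@labels)), c("pdms", "agarose"))
  # the bead is a centred disk: corner pixels are agarose, centre is pdms
  expect_equal(bead@labels[1, 1, 1], "agarose")
  expect_equal(bead@labels[6, 6, 1], "pdms")

  og <- makePhantom("oil_glass_edge", ScanGeometry(nx = 2, ny = 2, nz = 6, nFreq = 50))
  expect_equal(shiftGHz(og@materials$oil), 7.04)
  expect_length(og@materials$glass, 0)       # no in-range resonance
  expect_equal(unique(as.vector(og@labels[, , 1])), "oil")
  expect_equal(unique(as.vector(og@labels[, , 6])), "glass")

  w <- makePhantom("water", g)
  expect_equal(unique(as.vector(w@labels)), "water")
  expect_equal(shiftGHz(w@materials$water), 5.00)
  expect_equal(fwhmGHz(w@materials$water), 0.459)

  tl <- makePhantom("two_layer", g)
  expect_equal(length(tl@materials$both), 2L)
  expect_error(makePhantom("nope", g))
})

test_that("scan stream layout, determinism and displacement injection", {
  g <- ScanGeometry(nx = 8, ny = 6, nz = 2, nFreq = 40,
                    stageDelayMs = 100, pixelTimeMs = 20)
  ax <- makeFrequencyAxis(4, 6, 40)
  ph <- makePhantom("water", g)
  sim <- makeScanStream(ph, g, ax, snr = 25, seed = 3)
  expect_length(sim$stream, 40 * 8 * 6 * 2)
  sim2 <- makeScanStream(ph, g, ax, snr = 25, seed = 3)
  expect_identical(sim$stream, sim2$stream)
  # frequency is the fastest index: first nFreq samples are one spectrum
  simClean <- makeScanStream(ph, g, ax)
  expect_equal(simClean$stream[1:40], lorentzian(ax, waterPeak()))
  # 100 ms delay at 20 ms pixel time displaces every second line by 5 px
  gBead <- ScanGeometry(nx = 12, ny = 4, nz = 1, nFreq = 30, serpentine = FALSE,
                        stageDelayMs = 100, pixelTimeMs = 20)
  axB <- makeFrequencyAxis(3.5, 6, 30)
  phB <- makePhantom("bead_in_agarose", gBead, beadRadius = 3)
  simB <- makeScanStream(phB, gBead, axB)
  M <- reshapeStream(simB$stream, 30)
  specFor <- function(lab) lorentzian(axB, phB@materials[[lab]])
  # line 1 (0-based, second acquired line) of the plane: pixel content lags
  # the truth by 5 pixels
  line1cols <- 12 + (1:12)              # acquisition order, no serpentine
  truthLab <- phB@labels[, 2, 1]
  for (j in 6:12)
    expect_equal(M[, line1cols[j]], specFor(truthLab[j - 5]))
  expect_error(makeScanStream(phB, g, ax), "grid")
})

test_that("line displacement of a full line length is rejected", {
  g <- ScanGeometry(nx = 4, ny = 4, nz = 1, nFreq = 10,
                    stageDelayMs = 100, pixelTimeMs = 20)
  ph <- makePhantom("water", g)
  expect_error(makeScanStream(ph, g, makeFrequencyAxis(4, 6, 10)),
               "displacement")
})
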