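# Synthetic-data generators: every input the analysis pipeline needs can be
# produced here — noisy single spectra, repeated-acquisition series with
# shot-noise time scaling, ground-truth phantoms and serpentine raster
# streams. Noise is additive Gaussian referenced to the peak amplitude
# (SNR = max amplitude / sigma), matching the off-resonance-std SNR
# definition used for the instrument; sigma scales with integration time t
# as t^(-1/2) relative to a reference time (shot-noise limit).

#' Uniform frequency axis
#'
#' @param startGHz,endGHz axis limits in GHz (end > start).
#' @param nPoints number of points (>= 3); default 100, the typical number of
#'   frequency steps per 20 ms pixel.
#' @return Numeric vector of strictly increasing, uniformly spaced
#'   frequencies.
#' @examples
#' ax <- makeFrequencyAxis(4, 6, 100)
#' @export
makeFrequencyAxis <- function(startGHz, endGHz, nPoints = 100L) {
  stopIfNot(endGHz > startGHz, "endGHz must be > startGHz")
  stopIfNot(nPoints >= 3L, "nPoints must be >= 3")
  seq(startGHz, endGHz, length.out = as.integer(nPoints))
}

#' Default water resonance
#'
#' Single Lorentzian at 5.00 GHz with 0.459 GHz FWHM (the measured water
#' linewidth at 20 ms integration on this class of instrument) and unit
#' amplitude.
#'
#' @return A \code{\link{LorentzianPeaks}} of length 1.
#' @export
waterPeak <- function() LorentzianPeaks(5.00, 0.459, 1)

#' Generate one noisy SBG spectrum
#'
#' Noiseless sum-of-Lorentzians model plus i.i.d. zero-mean Gaussian noise
#' with standard deviation (max peak amplitude)/snr. The noise is
#' homoscedastic across the axis.
#'
#' @param freqGHz frequency axis (GHz), strictly increasing.
#' @param peaks a \code{\link{LorentzianPeaks}}.
#' @param snr target amplitude signal-to-noise ratio (> 0; \code{Inf} for a
#'   noiseless spectrum).
#' @param dcLevel photodetector DC level recorded with the spectrum (> 0).
#' @param integrationTimeMs integration time metadata (ms).
#' @param seed RNG seed (integer) or NULL; same seed, same spectrum.
#' @return A \code{\link{BrillouinSpectrum}}.
#' @examples
#' s <- makeSpectrum(makeFrequencyAxis(4, 6, 100), waterPeak(), snr = 38,
#'                   seed = 1)
#' @export
makeSpectrum <- function(freqGHz, peaks, snr = Inf, dcLevel = 100,
                         integrationTimeMs = 20, seed = NULL) {
  stopIfNot(length(snr) == 1L && !is.na(snr) && snr > 0, "snr must be > 0")
  model <- if (length(peaks)) lorentzian(freqGHz, peaks) else numeric(length(freqGHz))
  if (is.finite(snr)) {
    sigma <- if (length(peaks)) max(peaks@amplitude) / snr else 0
    model <- model + withSeed(seed, rnorm(length(freqGHz), 0, sigma))
  }
  BrillouinSpectrum(freqGHz = as.numeric(freqGHz), gain = model,
                    integrationTimeMs = integrationTimeMs, dcLevel = dcLevel,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Repeated-acquisition series with shot-noise time scaling
#'
#' Generates \code{nRepeats} spectra at each integration time. The noise
#' standard deviation at time t is sigma_ref * sqrt(refTimeMs / t), i.e. the
#' amplitude SNR grows as sqrt(t) (shot-noise limit), with sigma_ref =
#' amplitude/baseSnr at the reference time.
#'
#' @param freqGHz frequency axis (GHz).
#' @param peak a \code{\link{LorentzianPeaks}} (typically one peak).
#' @param nRepeats repeats per integration time (>= 2); 300 matches the
#'   instrument-characterization protocol.
#' @param integrationTimesMs vector of integration times (ms), all > 0.
#' @param baseSnr amplitude SNR at the reference time (default 38).
#' @param refTimeMs reference integration time (default 20 ms).
#' @param seed RNG seed or NULL.
#' @return A list with one element per integration time; each element is a
#'   list of \code{\link{BrillouinSpectrum}} objects of length
#'   \code{nRepeats}. The times are attached as the names (ms).
#' @export
makeSpectrumSeries <- function(freqGHz, peak, nRepeats = 300L,
                               integrationTimesMs = c(5, 10, 20, 40, 80),
                               baseSnr = 38, refTimeMs = 20, seed = NULL) {
  stopIfNot(all(integrationTimesMs > 0), "integration times must be > 0")
  stopIfNot(nRepeats >= 2L, "nRepeats must be >= 2")
  withSeed(seed, {
    out <- lapply(integrationTimesMs, function(t) {
      snrT <- baseSnr * sqrt(t / refTimeMs)
      lapply(seq_len(nRepeats), function(i)
        makeSpectrum(freqGHz, peak, snr = snrT, integrationTimeMs = t))
    })
    names(out) <- as.character(integrationTimesMs)
    out
  })
}

#' Ground-truth phantoms
#'
#' Standard test objects with known per-pixel resonances:
#' \describe{
#'   \item{water}{uniform single peak (5.00 GHz, 0.459 GHz FWHM) everywhere.}
#'   \item{bead_in_agarose}{a PDMS bead (4.07 GHz) disk centred in each plane,
#'     embedded in 1\% agarose (5.12 GHz); used for lateral-resolution edges.}
#'   \item{oil_glass_edge}{immersion oil (7.04 GHz) for the lower half of the
#'     z range, cover glass (resonance outside the scanned range, i.e. no
#'     in-range peak) above; used for the axial-resolution edge.}
#'   \item{two_layer}{two materials split along y (5.00 and 6.00 GHz) with an
#'     overlap stripe where both resonances are present, for multi-peak
#'     classification maps.}
#' }
#'
#' @param kind phantom kind, see above.
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param beadRadius bead radius in pixels (default nx/4).
#' @param overlapHalfWidth half-width (pixels) of the two_layer overlap
#'   stripe (default 1).
#' @return A \code{\link{PhantomSpec}}.
#' @examples
#' g <- ScanGeometry(nx = 8L, ny = 8L, nz = 1L, nFreq = 100L)
#' ph <- makePhantom("bead_in_agarose", g)
#' @export
makePhantom <- function(kind = c("water", "bead_in_agarose", "oil_glass_edge",
                                 "two_layer"),
                        geometry, beadRadius = NULL, overlapHalfWidth = 1L) {
  kind <- match.arg(kind)
  validObject(geometry)
  nx <- geometry@nx; ny <- geometry@ny; nz <- geometry@nz
  lab <- array("", c(nx, ny, nz))
  if (kind == "water") {
    lab[] <- "water"
    mats <- list(water = waterPeak())
  } else if (kind == "bead_in_agarose") {
    if (is.null(beadRadius)) beadRadius <- nx / 4
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+")
    plane <- ifelse(d2 <= beadRadius^2, "pdms", "agarose")
    lab[] <- rep(plane, nz)
    mats <- list(pdms = LorentzianPeaks(4.07, 0.35, 1),
                 agarose = LorentzianPeaks(5.12, 0.40, 1))
  } else if (kind == "oil_glass_edge") {
    zlab <- ifelse(seq_len(nz) <= ceiling(nz / 2), "oil", "glass")
    lab[] <- rep(zlab, each = nx * ny)
    mats <- list(oil = LorentzianPeaks(7.04, 0.50, 1),
                 glass = LorentzianPeaks(numeric(0), numeric(0), numeric(0)))
  } else { # two_layer
    cy <- (ny + 1) / 2
    ylab <- ifelse(seq_len(ny) < cy - overlapHalfWidth, "low",
                   ifelse(seq_len(ny) > cy + overlapHalfWidth, "high", "both"))
    lab[] <- rep(rep(ylab, each = nx), nz)
    mats <- list(low = LorentzianPeaks(5.00, 0.459, 1),
                 high = LorentzianPeaks(6.00, 0.459, 1),
                 both = LorentzianPeaks(c(5.00, 6.00), c(0.459, 0.459),
                                        c(1, 0.8)))
  }
  PhantomSpec(labels = lab, materials = mats)
}

#' Serpentine raster acquisition stream
#'
#' Simulates the 1-D acquisition stream of a raster scan over a phantom:
#' frequency is the fastest index; pixels follow the serpentine fast axis;
#' alternate z-planes are traversed in reversed row order when the z-flip
#' flag is set; and when the stage delay is positive the content of every
#' second line is displaced by round(stageDelayMs / pixelTimeMs) pixels along
#' the travel direction (the stage lags the commanded position). Gaussian
#' noise at the requested amplitude SNR is added to the whole stream.
#'
#' @param phantom a \code{\link{PhantomSpec}} matching the geometry grid.
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param freqGHz frequency axis of length \code{geometry@nFreq}.
#' @param snr amplitude SNR of the stream (\code{Inf} = noiseless).
#' @param dcLevel photodetector DC level metadata.
#' @param seed RNG seed or NULL.
#' @return A list with elements \code{stream} (numeric vector of length
#'   nFreq * nx * ny * nz), \code{geometry}, \code{freqGHz}, \code{dcLevel},
#'   and \code{truth}: per-pixel ground-truth arrays \code{shift},
#'   \code{fwhm}, \code{amplitude} (dominant in-range peak; NA where the
#'   material has none) and \code{label}.
#' @export
makeScanStream <- function(phantom, geometry, freqGHz, snr = Inf,
                           dcLevel = 100, seed = NULL) {
  validObject(phantom); validObject(geometry)
  dims <- c(geometry@nx, geometry@ny, geometry@nz)
  stopIfNot(identical(dim(phantom@labels), as.integer(dims)),
            "phantom grid does not match the scan geometry")
  stopIfNot(length(freqGHz) == geometry@nFreq,
            "freqGHz length must equal geometry nFreq")
  npix <- prod(dims)

  mats <- phantom@materials
  spec <- vapply(mats, function(p)
    if (length(p)) lorentzian(freqGHz, p) else numeric(length(freqGHz)),
    numeric(length(freqGHz)))
  labVec <- as.vector(phantom@labels)
  grid <- spec[, labVec, drop = FALSE]       # [nFreq x npix], grid order

  truth <- list(shift = array(NA_real_, dims), fwhm = array(NA_real_, dims),
                amplitude = array(NA_real_, dims), label = phantom@labels)
  for (nm in names(mats)) {
    p <- mats[[nm]]
    sel <- phantom@labels == nm
    if (length(p)) {
      k <- which.max(p@amplitude)
      truth$shift[sel] <- p@shiftGHz[k]
      truth$fwhm[sel] <- p@fwhmGHz[k]
      truth$amplitude[sel] <- p@amplitude[k]
    } else truth$amplitude[sel] <- 0
  }

  # Stage-delay displacement: inject into every second acquisition line.
  s <- round(geometry@stageDelayMs / geometry@pixelTimeMs)
  if (s > 0) {
    stopIfNot(s < geometry@nx, "line displacement >= line length")
    src <- if (geometry@shiftDirection > 0)
      pmax(seq_len(geometry@nx) - s, 1L)       # content lags the commanded position
    else
      pmin(seq_len(geometry@nx) + s, geometry@nx)
    for (ln in shiftedLines(geometry)) {
      cols <- lineColumns(geometry, ln)        # grid columns in travel order
      grid[, cols] <- grid[, cols[src]]
    }
  }

  ord <- as.vector(acquisitionOrder(geometry))
  stream <- as.vector(grid[, order(ord)])    # frequency fastest, acq order

  if (is.finite(snr)) {
    amps <- unlist(lapply(mats, function(p) p@amplitude))
    stopIfNot(length(amps) > 0 && max(amps) > 0,
              "finite snr requires a phantom with at least one peak")
    stopIfNot(snr > 0, "snr must be > 0")
    stream <- stream + withSeed(seed, rnorm(length(stream), 0, max(amps) / snr))
  }

  list(stream = stream, geometry = geometry, freqGHz = as.numeric(freqGHz),
       dcLevel = dcLevel, truth = truth)
}
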