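#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Brillouin resonances as Lorentzian peaks
#'
#' Vector-like container for one or more Brillouin resonances, each described
#' by its frequency shift \eqn{\Omega_B} (GHz), full width at half maximum
#' \eqn{\Gamma_B} (GHz) and peak amplitude (detector-referred, dimensionless).
#'
#' @slot shiftGHz numeric, peak center frequencies in GHz.
#' @slot fwhmGHz numeric, FWHM linewidths in GHz (strictly positive).
#' @slot amplitude numeric, non-negative peak amplitudes.
#'
#' @param shiftGHz,fwhmGHz,amplitude numeric vectors, recycled to a common
#'   length.
#' @return A \code{LorentzianPeaks} object.
#' @examples
#' water <- LorentzianPeaks(5.00, 0.459, 1)
#' shiftGHz(water)
#' @export LorentzianPeaks
#' @exportClass LorentzianPeaks
LorentzianPeaks <- setClass("LorentzianPeaks",
  slots = c(shiftGHz = "numeric", fwhmGHz = "numeric", amplitude = "numeric"))

setValidity("LorentzianPeaks", function(object) {
  n <- length(object@shiftGHz)
  if (length(object@fwhmGHz) != n || length(object@amplitude) != n)
    return("shiftGHz, fwhmGHz and amplitude must have equal length")
  # fwhm 0 is tolerated in the container (idealized undamped resonance, used
  # by the modulus conversion); the lineshape evaluators require fwhm > 0.
  if (any(!is.finite(object@fwhmGHz)) || any(object@fwhmGHz < 0))
    return("fwhmGHz must be finite and >= 0")
  if (any(object@amplitude < 0)) return("amplitude must be >= 0")
  TRUE
})

setMethod("initialize", "LorentzianPeaks", function(.Object, shiftGHz = numeric(0),
    fwhmGHz = numeric(0), amplitude = numeric(0), ...) {
  n <- max(length(shiftGHz), length(fwhmGHz), length(amplitude))
  if (n > 0) {
    shiftGHz <- rep_len(as.numeric(shiftGHz), n)
    fwhmGHz <- rep_len(as.numeric(fwhmGHz), n)
    amplitude <- rep_len(as.numeric(amplitude), n)
  }
  callNextMethod(.Object, shiftGHz = shiftGHz, fwhmGHz = fwhmGHz,
    amplitude = amplitude, ...)
})

#' Stimulated-gain scaling model
#'
#' Scaling of the stimulated Brillouin gain spectrum
#' \eqn{G(\Omega) = \pm\eta\, g(\Omega)\, l\, I_1}: pump-probe overlap
#' efficiency \code{eta}, interaction length \code{interactionLength} (um)
#' and pump intensity \code{pumpIntensity} (arbitrary units). Absolute gain
#' calibration is user-supplied; all three default to 1 so the spectrum is
#' detector-referred.
#'
#' @param eta overlap efficiency in [0, 1].
#' @param interactionLength interaction length in micrometres, > 0.
#' @param pumpIntensity pump intensity, >= 0 (arbitrary units).
#' @return A \code{GainModel} object.
#' @export
#' @exportClass GainModel
GainModel <- function(eta = 1, interactionLength = 1, pumpIntensity = 1)
  new("GainModel", eta = as.numeric(eta),
      interactionLength = as.numeric(interactionLength),
      pumpIntensity = as.numeric(pumpIntensity))

setClass("GainModel",
  slots = c(eta = "numeric", interactionLength = "numeric",
            pumpIntensity = "numeric"),
  prototype = prototype(eta = 1, interactionLength = 1, pumpIntensity = 1))

setValidity("GainModel", function(object) {
  if (object@eta < 0 || object@eta > 1) return("eta must be in [0, 1]")
  if (object@interactionLength <= 0) return("interactionLength must be > 0")
  if (object@pumpIntensity < 0) return("pumpIntensity must be >= 0")
  TRUE
})

#' Pulsed pump-probe scheme
#'
#' Pulse width, repetition rate and average powers of the pulsed SBS scheme.
#' The duty cycle dc = pulse width x repetition rate, the peak power
#' = average power / dc, and the SNR enhancement over a continuous-wave
#' scheme at equal average powers is E = 1/dc.
#'
#' @param pulseWidthNs pulse width in nanoseconds.
#' @param repRateMHz repetition rate in MHz.
#' @param avgPumpMw,avgProbeMw average pump/probe powers in mW.
#' @return A \code{PulseScheme} object.
#' @examples
#' ps <- PulseScheme(pulseWidthNs = 40, repRateMHz = 1.1, avgPumpMw = 13)
#' dutyCycle(ps)          # 0.044
#' enhancementFactor(ps)  # ~22.7
#' @export
#' @exportClass PulseScheme
PulseScheme <- function(pulseWidthNs, repRateMHz, avgPumpMw = NA_real_,
                        avgProbeMw = NA_real_)
  new("PulseScheme", pulseWidthNs = as.numeric(pulseWidthNs),
      repRateMHz = as.numeric(repRateMHz), avgPumpMw = as.numeric(avgPumpMw),
      avgProbeMw = as.numeric(avgProbeMw))

setClass("PulseScheme",
  slots = c(pulseWidthNs = "numeric", repRateMHz = "numeric",
            avgPumpMw = "numeric", avgProbeMw = "numeric"),
  prototype = prototype(avgPumpMw = NA_real_, avgProbeMw = NA_real_))

setValidity("PulseScheme", function(object) {
  if (object@pulseWidthNs <= 0) return("pulseWidthNs must be > 0")
  if (object@repRateMHz <= 0) return("repRateMHz must be > 0")
  dc <- object@pulseWidthNs * 1e-9 * object@repRateMHz * 1e6
  if (dc > 1 + 1e-12) return("pulse width exceeds the pulse period (duty cycle > 1)")
  TRUE
})

#' Optical constants of the probed material
#'
#' Refractive index n, mass density rho (kg/m^3) and pump wavelength
#' lambda_1 (nm), as needed to convert a Brillouin resonance into the complex
#' longitudinal modulus.
#'
#' @param refractiveIndex refractive index, > 1.
#' @param massDensity mass density in kg/m^3, > 0.
#' @param pumpWavelengthNm pump wavelength in nm, > 0.
#' @return A \code{MaterialOptics} object.
#' @examples
#' waterOptics <- MaterialOptics(1.33, 1000, 780.24)
#' @export
#' @exportClass MaterialOptics
MaterialOptics <- function(refractiveIndex, massDensity, pumpWavelengthNm)
  new("MaterialOptics", refractiveIndex = as.numeric(refractiveIndex),
      massDensity = as.numeric(massDensity),
      pumpWavelengthNm = as.numeric(pumpWavelengthNm))

setClass("MaterialOptics",
  slots = c(refractiveIndex = "numeric", massDensity = "numeric",
            pumpWavelengthNm = "numeric"))

setValidity("MaterialOptics", function(object) {
  if (object@refractiveIndex <= 1) return("refractiveIndex must be > 1")
  if (object@massDensity <= 0) return("massDensity must be > 0")
  if (object@pumpWavelengthNm <= 0) return("pumpWavelengthNm must be > 0")
  TRUE
})

#' Complex longitudinal modulus
#'
#' Storage (real) and loss (imaginary) parts of the complex longitudinal
#' modulus M* in pascal.
#'
#' @param storagePa,lossPa storage and loss moduli in Pa.
#' @return A \code{ComplexModulus} object.
#' @export
#' @exportClass ComplexModulus
ComplexModulus <- function(storagePa, lossPa)
  new("ComplexModulus", storagePa = as.numeric(storagePa),
      lossPa = as.numeric(lossPa))

setClass("ComplexModulus",
  slots = c(storagePa = "numeric", lossPa = "numeric"))

#' A single Brillouin gain spectrum
#'
#' Gain values on a calibrated frequency axis, with the acquisition metadata
#' needed downstream: integration time (ms), the photodetector DC level used
#' for gain normalization, and the RNG seed for synthetic spectra.
#'
#' @slot freqGHz numeric, strictly increasing frequency axis in GHz.
#' @slot gain numeric, one gain value per frequency.
#' @slot integrationTimeMs scalar, integration time in ms.
#' @slot dcLevel scalar, photodetector DC component (> 0, arbitrary units).
#' @slot seed integer or NA, generator seed for synthetic spectra.
#'
#' @param freqGHz,gain numeric vectors of equal length.
#' @param integrationTimeMs,dcLevel,seed see slots.
#' @return A \code{BrillouinSpectrum} object.
#' @export
#' @exportClass BrillouinSpectrum
BrillouinSpectrum <- function(freqGHz, gain, integrationTimeMs = 20,
                              dcLevel = 100, seed = NA_integer_)
  new("BrillouinSpectrum", freqGHz = as.numeric(freqGHz),
      gain = as.numeric(gain),
      integrationTimeMs = as.numeric(integrationTimeMs),
      dcLevel = as.numeric(dcLevel), seed = as.integer(seed))

setClass("BrillouinSpectrum",
  slots = c(freqGHz = "numeric", gain = "numeric",
            integrationTimeMs = "numeric", dcLevel = "numeric",
            seed = "integer"),
  prototype = prototype(integrationTimeMs = 20, dcLevel = 100,
                        seed = NA_integer_))

setValidity("BrillouinSpectrum", function(object) {
  if (length(object@gain) != length(object@freqGHz))
    return("gain and freqGHz must have equal length")
  if (length(object@freqGHz) >= 2 && any(diff(object@freqGHz) <= 0))
    return("freqGHz must be strictly increasing")
  if (!is.na(object@dcLevel) && object@dcLevel <= 0)
    return("dcLevel must be > 0")
  TRUE
})

#' Raster-scan geometry
#'
#' Scan grid dimensions and acquisition pattern of a raster-scanned SBS
#' acquisition: grid size, step sizes (um), per-pixel integration time (ms),
#' number of frequency points per spectrum, serpentine (bidirectional) fast
#' axis, alternate z-plane flipping, and the stage-delay that displaces every
#' second line.
#'
#' @param nx,ny,nz grid dimensions (>= 1); x is the fast axis.
#' @param stepX,stepY,stepZ pixel steps in micrometres.
#' @param pixelTimeMs per-pixel spectrum integration time in ms.
#' @param nFreq number of frequency points per spectrum.
#' @param serpentine logical; alternate fast-axis line direction.
#' @param zFlip logical; alternate z-planes traversed in reversed row order.
#' @param stageDelayMs stage settling delay displacing every second line.
#' @param shiftDirection +1 or -1, grid direction of the line displacement
#'   along the acquisition travel direction.
#' @return A \code{ScanGeometry} object.
#' @export
#' @exportClass ScanGeometry
ScanGeometry <- function(nx, ny, nz = 1L, stepX = 0.25, stepY = 0.25,
                         stepZ = 1, pixelTimeMs = 20, nFreq = 100L,
                         serpentine = TRUE, zFlip = TRUE, stageDelayMs = 0,
                         shiftDirection = 1)
  new("ScanGeometry", nx = as.integer(nx), ny = as.integer(ny),
      nz = as.integer(nz), stepX = as.numeric(stepX),
      stepY = as.numeric(stepY), stepZ = as.numeric(stepZ),
      pixelTimeMs = as.numeric(pixelTimeMs), nFreq = as.integer(nFreq),
      serpentine = as.logical(serpentine), zFlip = as.logical(zFlip),
      stageDelayMs = as.numeric(stageDelayMs),
      shiftDirection = as.numeric(shiftDirection))

setClass("ScanGeometry",
  slots = c(nx = "integer", ny = "integer", nz = "integer",
            stepX = "numeric", stepY = "numeric", stepZ = "numeric",
            pixelTimeMs = "numeric", nFreq = "integer",
            serpentine = "logical", zFlip = "logical",
            stageDelayMs = "numeric", shiftDirection = "numeric"),
  prototype = prototype(stepX = 0.25, stepY = 0.25, stepZ = 1,
                        pixelTimeMs = 20, serpentine = TRUE, zFlip = TRUE,
                        stageDelayMs = 0, shiftDirection = 1))

setValidity("ScanGeometry", function(object) {
  if (any(c(object@nx, object@ny, object@nz) < 1L))
    return("grid dimensions must be >= 1")
  if (object@pixelTimeMs <= 0) return("pixelTimeMs must be > 0")
  if (object@nFreq < 3L) return("nFreq must be >= 3")
  if (object@stageDelayMs < 0) return("stageDelayMs must be >= 0")
  if (!object@shiftDirection %in% c(-1, 1))
    return("shiftDirection must be +1 or -1")
  TRUE
})

#' Ground-truth phantom specification
#'
#' Per-pixel material labels over an (nx, ny, nz) grid together with a
#' material table mapping each label to its Brillouin resonances.
#'
#' @param labels character array (nx x ny x nz) of material labels.
#' @param materials named list of \code{\link{LorentzianPeaks}}, one entry per
#'   label occurring in \code{labels}. A material may carry zero peaks
#'   (no resonance inside the scanned range, e.g. cover glass).
#' @return A \code{PhantomSpec} object.
#' @export
#' @exportClass PhantomSpec
PhantomSpec <- function(labels, materials)
  new("PhantomSpec", labels = labels, materials = materials)

setClass("PhantomSpec",
  slots = c(labels = "array", materials = "list"))

setValidity("PhantomSpec", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3-D array")
  if (any(dim(object@labels) < 1L)) return("grid dims must be >= 1")
  lab <- unique(as.vector(object@labels))
  if (!all(lab %in% names(object@materials)))
    return(paste0("labels without material entry: ",
                  paste(setdiff(lab, names(object@materials)), collapse = ", ")))
  if (!all(vapply(object@materials, is, logical(1), "LorentzianPeaks")))
    return("materials must be LorentzianPeaks objects")
  TRUE
})

#' Hyperspectral Brillouin scan cube
#'
#' A \linkS4class{SummarizedExperiment} holding per-pixel Brillouin spectra as
#' a [frequency x pixels] \code{gain} assay. \code{rowData} carries the
#' frequency axis (\code{freq_ghz}), \code{colData} the grid coordinates
#' (\code{x}, \code{y}, \code{z}, 1-based), the acquisition position
#' \code{acq} and a logical \code{mask} for pixels without valid data (for
#' example vacated by the stage-delay line-shift correction). The
#' \code{\link{ScanGeometry}} lives in \code{metadata()$geometry}.
#'
#' @export
#' @exportClass SpectralCube
setClass("SpectralCube", contains = "SummarizedExperiment")

setValidity("SpectralCube", function(object) {
  g <- S4Vectors::metadata(object)$geometry
  if (is.null(g) || !is(g, "ScanGeometry"))
    return("metadata()$geometry must be a ScanGeometry")
  if (nrow(object) != g@nFreq)
    return("number of rows must equal geometry nFreq")
  if (ncol(object) != g@nx * g@ny * g@nz)
    return("number of pixels must equal nx * ny * nz")
  need <- c("x", "y", "z", "acq", "mask")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!"freq_ghz" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain freq_ghz")
  ax <- SummarizedExperiment::rowData(object)$freq_ghz
  if (any(diff(ax) <= 0)) return("freq_ghz must be strictly increasing")
  TRUE
})

#' @describeIn SpectralCube-class Construct a cube from a [frequency x pixels]
#'   gain matrix in grid pixel order (x fastest, then y, then z).
#' @param gain numeric matrix [nFreq x nPixels], pixels in grid order.
#' @param freqGHz numeric frequency axis (length nFreq).
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param mask logical vector of masked pixels (default none).
#' @return \code{SpectralCube()} returns a \code{SpectralCube}.
#' @export
SpectralCube <- function(gain, freqGHz, geometry, mask = NULL) {
  stopIfNot(is.matrix(gain), "'gain' must be a matrix [nFreq x nPixels]")
  npix <- geometry@nx * geometry@ny * geometry@nz
  stopIfNot(nrow(gain) == geometry@nFreq && ncol(gain) == npix,
            "gain matrix dimensions do not match the scan geometry")
  stopIfNot(length(freqGHz) == geometry@nFreq,
            "freqGHz length must equal geometry nFreq")
  if (is.null(mask)) mask <- rep(FALSE, npix)
  idx <- arrayInd(seq_len(npix), c(geometry@nx, geometry@ny, geometry@nz))
  acq <- as.vector(acquisitionOrder(geometry))
  se <- SummarizedExperiment(
    assays = list(gain = gain),
    rowData = DataFrame(freq_ghz = as.numeric(freqGHz)),
    colData = DataFrame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                        acq = acq, mask = as.logical(mask)),
    metadata = list(geometry = geometry))
  new("SpectralCube", se)
}

#' Result of a Lorentzian spectral fit
#'
#' Fitted peaks (sorted by ascending shift), constant baseline, per-parameter
#' standard errors, residual RMS, convergence and degeneracy flags.
#'
#' @slot peaks \code{\link{LorentzianPeaks}} sorted by ascending shift.
#' @slot baseline fitted constant offset.
#' @slot stdErrors numeric, standard errors named like the packed parameter
#'   vector (amplitude/shift/fwhm per peak + baseline); NA when unavailable.
#' @slot residualRms root-mean-square fit residual.
#' @slot converged logical convergence flag.
#' @slot degenerate logical; TRUE when two fitted centers fall within one
#'   axis step of each other.
#'
#' @export
#' @exportClass BrillouinFit
setClass("BrillouinFit",
  slots = c(peaks = "LorentzianPeaks", baseline = "numeric",
            stdErrors = "numeric", residualRms = "numeric",
            converged = "logical", degenerate = "logical"))

setValidity("BrillouinFit", function(object) {
  s <- object@peaks@shiftGHz
  if (length(s) >= 2 && any(diff(s) < 0)) return("peaks must be sorted by shift")
  if (length(object@residualRms) && !is.na(object@residualRms) &&
      object@residualRms < 0)
    return("residualRms must be >= 0")
  TRUE
})

#' Single/multi-peak classification of a spectrum
#'
#' Outcome of the derivative-offset test: the label, the number of derivative
#' zero crossings at zero offset, the swept offsets with their extra-crossing
#' indicators, and the multi-peak metric (fraction of offsets detecting extra
#' crossings, in [0, 1]; single-peak spectra have metric 0 exactly).
#'
#' @export
#' @exportClass PeakClassification
setClass("PeakClassification",
  slots = c(label = "character", nExtremaZeroOffset = "integer",
            offsets = "numeric", detections = "logical", metric = "numeric",
            fitFailed = "logical"))

setValidity("PeakClassification", function(object) {
  if (!object@label %in% c("single", "multi"))
    return("label must be 'single' or 'multi'")
  if (length(object@offsets) != length(object@detections))
    return("offsets and detections must have equal length")
  if (object@metric < 0 || object@metric > 1) return("metric must be in [0, 1]")
  if ((object@metric > 0) != (object@label == "multi"))
    return("label must be 'multi' iff metric > 0")
  TRUE
})

#' Assembled per-pixel Brillouin maps
#'
#' Per-pixel images of Brillouin shift (GHz), linewidth (GHz), amplitude,
#' gain G_B, SNR, number of fitted peaks and (optionally) the multi-peak
#' metric, each an (nx, ny, nz) array, plus the mask of failed or vacated
#' pixels. Masked pixels carry NA in every map.
#'
#' @slot maps named list of numeric (nx, ny, nz) arrays.
#' @slot mask logical (nx, ny, nz) array; TRUE where no valid value exists.
#' @slot geometry the \code{\link{ScanGeometry}} of the scan.
#'
#' @export
#' @exportClass BrillouinMaps
setClass("BrillouinMaps",
  slots = c(maps = "list", mask = "array", geometry = "ScanGeometry"))

setValidity("BrillouinMaps", function(object) {
  dims <- c(object@geometry@nx, object@geometry@ny, object@geometry@nz)
  if (!identical(dim(object@mask), as.integer(dims)))
    return("mask dimensions must match the geometry")
  for (nm in names(object@maps)) {
    if (!identical(dim(object@maps[[nm]]), as.integer(dims)))
      return(paste0("map '", nm, "' dimensions must match the geometry"))
    if (any(!is.na(object@maps[[nm]][object@mask])))
      return(paste0("map '", nm, "' must be NA on masked pixels"))
  }
  TRUE
})

#' Precision-versus-integration-time curve
#'
#' Sample standard deviation of fitted Brillouin shift and linewidth at each
#' integration time, from repeated synthetic acquisitions.
#'
#' @slot timesMs strictly increasing integration times (ms).
#' @slot shiftSdGHz,widthSdGHz per-time standard deviations (GHz).
#' @slot nRepeats repeats per time point.
#'
#' @export
#' @exportClass PrecisionCurve
setClass("PrecisionCurve",
  slots = c(timesMs = "numeric", shiftSdGHz = "numeric",
            widthSdGHz = "numeric", nRepeats = "integer"))

setValidity("PrecisionCurve", function(object) {
  if (any(diff(object@timesMs) <= 0)) return("timesMs must be strictly increasing")
  n <- length(object@timesMs)
  if (length(object@shiftSdGHz) != n || length(object@widthSdGHz) != n)
    return("per-time vectors must match timesMs length")
  if (any(c(object@shiftSdGHz, object@widthSdGHz) < 0, na.rm = TRUE))
    return("standard deviations must be >= 0")
  if (any(object@nRepeats < 2L)) return("nRepeats must be >= 2")
  TRUE
})
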