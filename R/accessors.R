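#' @describeIn LorentzianPeaks-class peak center frequencies (GHz)
#' @param x a \code{LorentzianPeaks} object
#' @export
setMethod("shiftGHz", "LorentzianPeaks", function(x) x@shiftGHz)

#' @describeIn LorentzianPeaks-class FWHM linewidths (GHz)
#' @export
setMethod("fwhmGHz", "LorentzianPeaks", function(x) x@fwhmGHz)

#' @describeIn LorentzianPeaks-class peak amplitudes
#' @export
setMethod("amplitude", "LorentzianPeaks", function(x) x@amplitude)

#' @export
setMethod("length", "LorentzianPeaks", function(x) length(x@shiftGHz))

#' @export
setMethod("[", "LorentzianPeaks", function(x, i, j, ..., drop = TRUE)
  LorentzianPeaks(x@shiftGHz[i], x@fwhmGHz[i], x@amplitude[i]))

#' @export
setMethod("as.data.frame", "LorentzianPeaks", function(x, ...)
  data.frame(shift_ghz = x@shiftGHz, fwhm_ghz = x@fwhmGHz,
             amplitude = x@amplitude))

setMethod("show", "LorentzianPeaks", function(object) {
  cat("LorentzianPeaks with", length(object), "peak(s)\n")
  if (length(object)) print(as.data.frame(object), row.names = FALSE)
})

#' @describeIn BrillouinSpectrum-class frequency axis in GHz
#' @param x a \code{BrillouinSpectrum}
#' @export
setMethod("frequencyAxis", "BrillouinSpectrum", function(x) x@freqGHz)

#' @describeIn BrillouinSpectrum-class gain values
#' @export
setMethod("gainValues", "BrillouinSpectrum", function(x) x@gain)

#' @describeIn BrillouinSpectrum-class photodetector DC level
#' @export
setMethod("dcLevel", "BrillouinSpectrum", function(x) x@dcLevel)

#' @describeIn BrillouinSpectrum-class integration time in ms
#' @export
setMethod("integrationTimeMs", "BrillouinSpectrum", function(x) x@integrationTimeMs)

setMethod("show", "BrillouinSpectrum", function(object) {
  n <- length(object@freqGHz)
  cat(sprintf("BrillouinSpectrum: %d points, %.4g-%.4g GHz, %g ms integration\n",
              n, min(object@freqGHz), max(object@freqGHz),
              object@integrationTimeMs))
})

#' @describeIn SpectralCube-class the scan geometry
#' @param x a \code{SpectralCube}
#' @export
setMethod("scanGeometry", "SpectralCube", function(x)
  S4Vectors::metadata(x)$geometry)

#' @describeIn SpectralCube-class frequency axis in GHz
#' @export
setMethod("frequencyAxis", "SpectralCube", function(x)
  SummarizedExperiment::rowData(x)$freq_ghz)

#' @describeIn SpectralCube-class logical vector of masked pixels
#' @export
setMethod("pixelMask", "SpectralCube", function(x)
  SummarizedExperiment::colData(x)$mask)

setMethod("show", "SpectralCube", function(object) {
  g <- scanGeometry(object)
  cat(sprintf("SpectralCube: %d x %d x %d pixels, %d frequency points (%.4g-%.4g GHz), %d masked\n",
              g@nx, g@ny, g@nz, g@nFreq, min(frequencyAxis(object)),
              max(frequencyAxis(object)), sum(pixelMask(object))))
})

#' @describeIn PulseScheme-class duty cycle (fraction)
#' @param x a \code{PulseScheme}
#' @export
setMethod("dutyCycle", "PulseScheme", function(x)
  dutyCycle(x@pulseWidthNs, x@repRateMHz))

#' @describeIn PulseScheme-class SNR enhancement E = 1/dc over CW
#' @export
setMethod("enhancementFactor", "PulseScheme", function(x)
  enhancementFactor(dutyCycle(x)))

setMethod("show", "PulseScheme", function(object) {
  dc <- dutyCycle(object)
  cat(sprintf("PulseScheme: %g ns @ %g MHz (duty cycle %.3g%%, E = %.3g)\n",
              object@pulseWidthNs, object@repRateMHz, 100 * dc, 1 / dc))
  if (!is.na(object@avgPumpMw))
    cat(sprintf("  avg pump %g mW (peak %.4g mW)", object@avgPumpMw,
                object@avgPumpMw / dc))
  if (!is.na(object@avgProbeMw)) cat(sprintf(", avg probe %g mW", object@avgProbeMw))
  if (!is.na(object@avgPumpMw) || !is.na(object@avgProbeMw)) cat("\n")
})

#' @describeIn ComplexModulus-class storage modulus (Pa)
#' @param x a \code{ComplexModulus}
#' @export
setMethod("storagePa", "ComplexModulus", function(x) x@storagePa)

#' @describeIn ComplexModulus-class loss modulus (Pa)
#' @export
setMethod("lossPa", "ComplexModulus", function(x) x@lossPa)

setMethod("show", "ComplexModulus", function(object)
  cat(sprintf("ComplexModulus: storage %.4g GPa, loss %.4g GPa\n",
              object@storagePa / 1e9, object@lossPa / 1e9)))

#' @describeIn BrillouinFit-class fitted peaks, sorted by ascending shift
#' @param x a \code{BrillouinFit}
#' @export
setMethod("peaks", "BrillouinFit", function(x) x@peaks)

#' @describeIn BrillouinFit-class fitted constant baseline
#' @export
setMethod("baseline", "BrillouinFit", function(x) x@baseline)

#' @describeIn BrillouinFit-class convergence flag
#' @export
setMethod("converged", "BrillouinFit", function(x) x@converged)

#' @describeIn BrillouinFit-class number of fitted peaks
#' @export
setMethod("nPeaks", "BrillouinFit", function(x) length(x@peaks))

#' @describeIn BrillouinFit-class root-mean-square residual
#' @export
setMethod("residualRms", "BrillouinFit", function(x) x@residualRms)

#' @describeIn BrillouinFit-class TRUE when fitted centers are closer than
#'   one axis step
#' @export
setMethod("isDegenerate", "BrillouinFit", function(x) x@degenerate)

setMethod("show", "BrillouinFit", function(object) {
  cat(sprintf("BrillouinFit: %d peak(s), converged = %s%s\n",
              nPeaks(object), object@converged,
              if (object@degenerate) " (degenerate)" else ""))
  if (length(object@peaks)) print(as.data.frame(object@peaks), row.names = FALSE)
  cat(sprintf("  baseline %.4g, residual rms %.4g\n", object@baseline,
              object@residualRms))
})

#' @describeIn PeakClassification-class "single" or "multi"
#' @param x a \code{PeakClassification}
#' @export
setMethod("classificationLabel", "PeakClassification", function(x) x@label)

#' @describeIn PeakClassification-class fraction of swept offsets detecting
#'   extra zero crossings
#' @export
setMethod("multiPeakMetric", "PeakClassification", function(x) x@metric)

setMethod("show", "PeakClassification", function(object)
  cat(sprintf("PeakClassification: %s (metric %.3g, %d extrema at zero offset)\n",
              object@label, object@metric, object@nExtremaZeroOffset)))

#' @describeIn BrillouinMaps-class extract one per-pixel map
#' @param x a \code{BrillouinMaps}
#' @param which map name, one of \code{names(x@maps)} such as "shift",
#'   "linewidth", "amplitude", "gain", "snr", "n_peaks", "metric"
#' @export
setMethod("brillouinMap", "BrillouinMaps", function(x, which) {
  stopIfNot(which %in% names(x@maps),
            paste0("no map '", which, "'; available: ",
                   paste(names(x@maps), collapse = ", ")))
  x@maps[[which]]
})

#' @describeIn BrillouinMaps-class the scan geometry
#' @export
setMethod("scanGeometry", "BrillouinMaps", function(x) x@geometry)

#' @describeIn BrillouinMaps-class logical array of masked pixels
#' @export
setMethod("pixelMask", "BrillouinMaps", function(x) x@mask)

setMethod("show", "BrillouinMaps", function(object) {
  g <- object@geometry
  cat(sprintf("BrillouinMaps: %d x %d x %d, maps: %s; %d masked pixel(s)\n",
              g@nx, g@ny, g@nz, paste(names(object@maps), collapse = ", "),
              sum(object@mask)))
})

setMethod("show", "PrecisionCurve", function(object) {
  cat("PrecisionCurve:\n")
  print(data.frame(time_ms = object@timesMs,
                   shift_sd_ghz = object@shiftSdGHz,
                   width_sd_ghz = object@widthSdGHz,
                   n = object@nRepeats), row.names = FALSE)
})

#' @export
setMethod("as.data.frame", "PrecisionCurve", function(x, ...)
  data.frame(time_ms = x@timesMs, shift_sd_ghz = x@shiftSdGHz,
             width_sd_ghz = x@widthSdGHz, n = x@nRepeats))
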