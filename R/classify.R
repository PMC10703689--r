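# Single- versus multi-peak classification by the derivative-offset test:
# the analytic derivative of the fitted two-Lorentzian model is normalized
# by its maximum absolute value, a scalar offset is added, and the zero
# crossings are counted. A unimodal lineshape crosses zero exactly once at
# zero offset and exactly twice at any offset in (0, 1) of either sign
# (the normalized derivative returns to zero in both tails), so any count
# beyond that baseline reveals a second extremum or a shoulder "bump".
# Normalizing makes the canonical [-0.5, +0.5] sweep range scale-free.

#' Zero crossings of the offset, normalized model derivative
#'
#' Evaluates the analytic derivative of the fitted sum of Lorentzians on a
#' dense uniform grid spanning \code{freqRange}, divides it by its maximum
#' absolute value, adds \code{offset}, and counts sign changes. Crossings
#' within one grid step of either boundary are ignored (finite-scan-range
#' edge effects).
#'
#' @param fit a converged \code{\link{BrillouinFit}}.
#' @param offset scalar offset in normalized-derivative units.
#' @param freqRange c(lo, hi) GHz range to scan (e.g. the spectrum axis
#'   range).
#' @param nGrid number of grid points (default 2001).
#' @return Integer number of zero crossings.
#' @examples
#' s <- makeSpectrum(makeFrequencyAxis(4, 6, 100), waterPeak())
#' f <- fitMultiLorentzian(s, 2)
#' countDerivativeZeroCrossings(f, 0, c(4, 6))   # 1: unimodal
#' @export
countDerivativeZeroCrossings <- function(fit, offset = 0, freqRange,
                                         nGrid = 2001L) {
  stopIfNot(is(fit, "BrillouinFit"), "'fit' must be a BrillouinFit")
  stopIfNot(converged(fit), "fit has not converged")
  stopIfNot(length(freqRange) == 2L && freqRange[1] < freqRange[2],
            "freqRange must be c(lo, hi)")
  x <- seq(freqRange[1], freqRange[2], length.out = as.integer(nGrid))
  d <- lorentzianDeriv(x, peaks(fit))
  m <- max(abs(d))
  if (m == 0) return(0L)
  f <- d / m + offset
  # sign changes, robust to exact zeros on the grid (a zero counts as a
  # crossing only when the surrounding signs differ)
  s <- sign(f)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(0L)
  ch <- which(s[nz][-length(nz)] != s[nz][-1L])
  pos <- (nz[ch] + nz[ch + 1L]) / 2
  pos <- pos[pos > 2 & pos < length(f) - 1]   # ignore boundary-adjacent
  length(pos)
}

# Expected crossing count of a unimodal lineshape at a given offset.
unimodalCrossings <- function(offset) if (abs(offset) < 1e-9) 1L else 2L

#' Classify a spectrum as single- or multi-peak
#'
#' Fits a two-Lorentzian model and applies the derivative-offset test: the
#' spectrum is labeled "multi" if the normalized model derivative has more
#' than one zero crossing at zero offset (two or more local extrema), or if
#' extra crossings beyond the unimodal expectation appear at any offset of
#' the sweep (a shoulder "bump" on the flank of a single maximum). The
#' multi-peak metric is the fraction of swept offsets that detect extra
#' crossings; it is 0 exactly for spectra labeled "single". A failed fit
#' yields label "single" with metric 0 and the fit-failure flag set.
#'
#' Only significant fitted components enter the derivative test: a fitted
#' Lorentzian whose amplitude is indistinguishable from the spectrum's noise
#' floor cannot attest a second mechanical component. The amplitude
#' threshold is set by the classifier's design false-positive rate
#' \code{alpha} (default 0.001, i.e. 99.9\% of pure single-peak spectra are
#' expected to classify as single), Bonferroni-corrected over the number of
#' spectral resolution elements in the scan range.
#'
#' @param spectrum a \code{\link{BrillouinSpectrum}}.
#' @param offsets sweep offsets in normalized-derivative units; default 21
#'   evenly spaced values in [-0.5, +0.5].
#' @param nGrid dense-grid size for the crossing count.
#' @param alpha design false-positive (spurious "multi") rate on pure
#'   single-peak spectra.
#' @param minFwhmGHz FWHM floor passed to \code{\link{fitMultiLorentzian}};
#'   also sets the width of a spectral resolution element.
#' @return A \code{\link{PeakClassification}}.
#' @examples
#' ax <- makeFrequencyAxis(4, 7, 150)
#' one <- makeSpectrum(ax, waterPeak())
#' classificationLabel(classifySpectrum(one))   # "single"
#' two <- makeSpectrum(ax, LorentzianPeaks(c(5.03, 5.8), 0.46, c(1, 0.8)))
#' classificationLabel(classifySpectrum(two))   # "multi"
#' @export
classifySpectrum <- function(spectrum,
                             offsets = seq(-0.5, 0.5, length.out = 21L),
                             nGrid = 2001L, alpha = 0.001,
                             minFwhmGHz = 0.15) {
  fit <- fitMultiLorentzian(spectrum, 2L, minFwhmGHz = minFwhmGHz)
  singleOut <- function(failed) new("PeakClassification", label = "single",
      nExtremaZeroOffset = if (failed) 0L else 1L, offsets = offsets,
      detections = rep(FALSE, length(offsets)), metric = 0,
      fitFailed = failed)
  if (!converged(fit)) return(singleOut(TRUE))
  rng <- range(spectrum@freqGHz)
  # amplitude significance screen (Bonferroni over resolution elements)
  m <- max(1, ceiling(diff(rng) / minFwhmGHz))
  thr <- stats::qnorm(1 - alpha / m) * noiseScale(spectrum@gain)
  keep <- amplitude(peaks(fit)) >= thr
  if (!any(keep)) return(singleOut(FALSE))
  testFit <- new("BrillouinFit", peaks = peaks(fit)[which(keep)],
                 baseline = baseline(fit), stdErrors = NA_real_,
                 residualRms = residualRms(fit), converged = TRUE,
                 degenerate = isDegenerate(fit))
  counts <- vapply(offsets, function(o)
    countDerivativeZeroCrossings(testFit, o, rng, nGrid), integer(1))
  det <- counts > vapply(offsets, unimodalCrossings, integer(1))
  n0 <- countDerivativeZeroCrossings(testFit, 0, rng, nGrid)
  metric <- mean(det)
  new("PeakClassification",
      label = if (metric > 0) "multi" else "single",
      nExtremaZeroOffset = max(n0, 1L), offsets = offsets, detections = det,
      metric = metric, fitFailed = FALSE)
}

#' Per-pixel multi-peak metric map
#'
#' Assembles the per-pixel multi-peak metric into an (nx, ny, nz) image.
#' Pixels labeled "single" are exactly 0; missing or masked pixels are NA
#' (masked, never interpolated).
#'
#' @param classifications list of \code{\link{PeakClassification}} (or NULL)
#'   per grid pixel.
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param mask optional logical array of additionally masked pixels.
#' @return Numeric (nx, ny, nz) array of metric values.
#' @export
multiPeakMetricMap <- function(classifications, geometry, mask = NULL) {
  dims <- c(geometry@nx, geometry@ny, geometry@nz)
  stopIfNot(length(classifications) == prod(dims),
            "one classification (or NULL) per grid pixel is required")
  out <- array(NA_real_, dims)
  for (p in seq_along(classifications)) {
    cl <- classifications[[p]]
    if (is.null(cl)) next
    if (!is.null(mask) && mask[p]) next
    out[p] <- multiPeakMetric(cl)
  }
  out
}
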