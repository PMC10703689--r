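# Scan reconstruction: turn a 1-D acquisition stream back into per-pixel
# spectra in phantom (grid) coordinates, undoing serpentine traversal,
# stage-delay line displacement and alternate-plane flips. Reconstruction is
# a pure permutation + masking of the stream samples.

# Acquisition position (1-based) of every grid pixel. Traversal: planes in z
# order; within a plane, rows in y order (reversed on odd planes when zFlip);
# within a row, x forward, reversed on every second acquired line when
# serpentine. Line parity is counted from line 0 in acquisition order.
acquisitionOrder <- function(geom) {
  nx <- geom@nx; ny <- geom@ny; nz <- geom@nz
  arr <- array(0L, c(nx, ny, nz))
  pos <- 1L
  for (iz0 in seq_len(nz) - 1L) {
    for (ry0 in seq_len(ny) - 1L) {
      iy0 <- if (geom@zFlip && iz0 %% 2L == 1L) ny - 1L - ry0 else ry0
      lineIdx <- iz0 * ny + ry0
      xs <- if (geom@serpentine && lineIdx %% 2L == 1L) rev(seq_len(nx)) else seq_len(nx)
      arr[xs, iy0 + 1L, iz0 + 1L] <- seq.int(pos, pos + nx - 1L)
      pos <- pos + nx
    }
  }
  arr
}

# Lines affected by the stage delay: every second acquired line (odd global
# line index, counted from 0).
shiftedLines <- function(geom) {
  out <- list()
  for (iz0 in seq_len(geom@nz) - 1L)
    for (ry0 in seq_len(geom@ny) - 1L)
      if ((iz0 * geom@ny + ry0) %% 2L == 1L)
        out[[length(out) + 1L]] <- c(iz0 = iz0, ry0 = ry0)
  out
}

# Grid-order column indices of one acquired line, listed in travel order.
lineColumns <- function(geom, ln) {
  nx <- geom@nx; ny <- geom@ny
  iz0 <- ln[["iz0"]]; ry0 <- ln[["ry0"]]
  iy0 <- if (geom@zFlip && iz0 %% 2L == 1L) ny - 1L - ry0 else ry0
  lineIdx <- iz0 * ny + ry0
  xs <- if (geom@serpentine && lineIdx %% 2L == 1L) rev(seq_len(nx)) else seq_len(nx)
  xs + nx * iy0 + nx * ny * iz0
}

#' Reshape an acquisition stream to [frequency x pixels]
#'
#' Column p (1-based) holds the stream samples
#' \code{[(p-1)*nFreq + 1, p*nFreq]}; frequency is the fastest index of the
#' stream. Pixels are left in acquisition order.
#'
#' @param stream numeric acquisition stream.
#' @param nFreq number of frequency points per spectrum.
#' @return A numeric matrix [nFreq x nPixels].
#' @examples
#' m <- reshapeStream(1:600, 100L)  # 100 x 6
#' @export
reshapeStream <- function(stream, nFreq) {
  nFreq <- as.integer(nFreq)
  stopIfNot(nFreq >= 1L, "nFreq must be >= 1")
  r <- length(stream) %% nFreq
  if (r != 0L)
    stop(sprintf("stream length %d is not divisible by nFreq = %d (remainder %d)",
                 length(stream), nFreq, r))
  matrix(stream, nrow = nFreq)
}

#' Flip alternate z-planes
#'
#' Reverses odd-indexed planes (counting from 0, i.e. the 2nd, 4th, ...)
#' along the y axis, undoing the bidirectional z-scan pattern. Applying the
#' operation twice is the identity.
#'
#' @param x a 3-D array (nx, ny, nz).
#' @return The array with alternate planes flipped.
#' @export
flipAlternatePlanes <- function(x) {
  stopIfNot(length(dim(x)) == 3L, "'x' must be a 3-D array (nx, ny, nz)")
  nz <- dim(x)[3L]
  for (iz in seq_len(nz)) if ((iz - 1L) %% 2L == 1L)
    x[, , iz] <- x[, dim(x)[2L]:1L, iz]
  x
}

#' @describeIn SpectralCube-class Undo the stage-delay line displacement:
#'   every second acquired line is shifted back by
#'   s = round(stageDelayMs / pixelTimeMs) pixels along its travel direction;
#'   the s vacated pixels at the line end are masked (their content was never
#'   acquired), not wrapped.
#' @param stageDelayMs,pixelTimeMs optional overrides of the geometry values.
#' @param ... unused.
#' @export
setMethod("correctLineShift", "SpectralCube",
  function(x, stageDelayMs = NULL, pixelTimeMs = NULL, ...) {
    geom <- scanGeometry(x)
    if (is.null(stageDelayMs)) stageDelayMs <- geom@stageDelayMs
    if (is.null(pixelTimeMs)) pixelTimeMs <- geom@pixelTimeMs
    stopIfNot(stageDelayMs >= 0, "stageDelayMs must be >= 0")
    stopIfNot(pixelTimeMs > 0, "pixelTimeMs must be > 0")
    s <- as.integer(round(stageDelayMs / pixelTimeMs))
    if (s == 0L) return(x)
    nx <- geom@nx
    stopIfNot(s < nx, "line displacement is >= the line length")
    A <- SummarizedExperiment::assay(x, "gain")
    mask <- pixelMask(x)
    for (ln in shiftedLines(geom)) {
      cols <- lineColumns(geom, ln)
      if (geom@shiftDirection > 0) {
        keep <- seq_len(nx - s)
        A[, cols[keep]] <- A[, cols[keep + s]]
        vac <- cols[(nx - s + 1L):nx]
      } else {
        keep <- (s + 1L):nx
        A[, cols[keep]] <- A[, cols[keep - s]]
        vac <- cols[seq_len(s)]
      }
      A[, vac] <- NA_real_
      mask[vac] <- TRUE
    }
    SpectralCube(A, frequencyAxis(x), geom, mask = mask)
  })

#' Reconstruct a scan cube from an acquisition stream
#'
#' Reshapes the 1-D stream to [frequency x pixels], reorders pixels from
#' acquisition order to grid order (undoing the serpentine fast axis and
#' alternate-plane flips), and corrects the stage-delay line displacement
#' (masking vacated pixels). Optionally applies the zero-phase high-pass
#' detrend to the stream first.
#'
#' @param stream numeric acquisition stream (or the list returned by
#'   \code{\link{makeScanStream}}, in which case geometry and axis are taken
#'   from it).
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param freqGHz frequency axis of length \code{geometry@nFreq}.
#' @param detrendCutoffHz high-pass cutoff in Hz applied to the stream before
#'   reshaping, or NULL (default) for no filtering.
#' @param correctShift apply the line-shift correction (default TRUE).
#' @return A \code{\link{SpectralCube}} in grid order.
#' @examples
#' g <- ScanGeometry(nx = 6L, ny = 4L, nz = 2L, nFreq = 50L)
#' ax <- makeFrequencyAxis(4, 6, 50)
#' sim <- makeScanStream(makePhantom("water", g), g, ax)
#' cube <- reconstructScan(sim)
#' @export
reconstructScan <- function(stream, geometry = NULL, freqGHz = NULL,
                            detrendCutoffHz = NULL, correctShift = TRUE) {
  if (is.list(stream)) {
    if (is.null(geometry)) geometry <- stream$geometry
    if (is.null(freqGHz)) freqGHz <- stream$freqGHz
    stream <- stream$stream
  }
  stopIfNot(is(geometry, "ScanGeometry"), "'geometry' must be a ScanGeometry")
  if (!is.null(detrendCutoffHz)) {
    rate <- geometry@nFreq / (geometry@pixelTimeMs / 1000)
    stream <- detrendHighpass(stream, rate, detrendCutoffHz)
  }
  M <- reshapeStream(stream, geometry@nFreq)
  npix <- geometry@nx * geometry@ny * geometry@nz
  stopIfNot(ncol(M) == npix, "stream pixel count does not match the geometry")
  ord <- as.vector(acquisitionOrder(geometry))
  cube <- SpectralCube(M[, ord, drop = FALSE], freqGHz, geometry)
  if (correctShift && geometry@stageDelayMs > 0) cube <- correctLineShift(cube)
  cube
}

#' Fit every pixel spectrum of a cube
#'
#' Runs the single- or multi-Lorentzian fit on each unmasked pixel of a
#' \code{\link{SpectralCube}}, optionally estimating the per-pixel SNR and
#' running the single/multi-peak classifier.
#'
#' @param cube a \code{\link{SpectralCube}}.
#' @param nPeaks 1, 2 or 3 Lorentzians per pixel.
#' @param noiseWindow optional c(lo, hi) GHz window for
#'   \code{\link{estimateSNR}} (must lie outside the fitted peaks).
#' @param classify run \code{\link{classifySpectrum}} per pixel.
#' @param dcLevel photodetector DC level for gain normalization.
#' @param ... passed to the per-spectrum fitting functions.
#' @return A list with \code{fits} (list of \code{\link{BrillouinFit}} or
#'   NULL for masked pixels), \code{snr} (numeric or NULL),
#'   \code{classifications} (list or NULL), \code{dcLevel} and the
#'   \code{geometry}.
#' @export
fitCube <- function(cube, nPeaks = 1L, noiseWindow = NULL, classify = FALSE,
                    dcLevel = 100, ...) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  stopIfNot(nPeaks %in% 1:3, "nPeaks must be 1, 2 or 3")
  A <- SummarizedExperiment::assay(cube, "gain")
  ax <- frequencyAxis(cube)
  mask <- pixelMask(cube)
  fits <- vector("list", ncol(A))
  cls <- if (classify) vector("list", ncol(A)) else NULL
  snr <- if (!is.null(noiseWindow)) rep(NA_real_, ncol(A)) else NULL
  for (p in seq_len(ncol(A))) {
    if (mask[p]) next
    sp <- BrillouinSpectrum(freqGHz = ax, gain = A[, p], dcLevel = dcLevel)
    fits[[p]] <- if (nPeaks == 1L) fitLorentzian(sp, ...)
                 else fitMultiLorentzian(sp, nPeaks = nPeaks, ...)
    if (!is.null(snr) && converged(fits[[p]]))
      snr[p] <- tryCatch(estimateSNR(sp, fits[[p]], noiseWindow),
                         error = function(e) NA_real_)
    if (classify) cls[[p]] <- classifySpectrum(sp)
  }
  list(fits = fits, snr = snr, classifications = cls, dcLevel = dcLevel,
       geometry = scanGeometry(cube))
}

#' Assemble per-pixel Brillouin maps
#'
#' Builds \code{\link{BrillouinMaps}} from per-pixel fit results in grid
#' order. Multi-peak pixels contribute their highest-amplitude peak to the
#' scalar shift/linewidth/amplitude maps (all peaks remain available in the
#' fits). Pixels with a NULL or non-converged fit are masked, never
#' interpolated.
#'
#' @param fits list of \code{\link{BrillouinFit}} (or NULL) per grid pixel,
#'   e.g. from \code{\link{fitCube}} (the whole \code{fitCube} result can be
#'   passed directly).
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param dcLevel DC level for the gain map (NA suppresses the map).
#' @param snr optional per-pixel SNR vector.
#' @param classifications optional per-pixel \code{\link{PeakClassification}}
#'   list; adds the multi-peak "metric" map.
#' @return A \code{\link{BrillouinMaps}}.
#' @export
buildMaps <- function(fits, geometry = NULL, dcLevel = NA_real_, snr = NULL,
                      classifications = NULL) {
  if (is.list(fits) && !is.null(fits$fits)) {
    if (is.null(geometry)) geometry <- fits$geometry
    if (is.na(dcLevel)) dcLevel <- fits$dcLevel
    if (is.null(snr)) snr <- fits$snr
    if (is.null(classifications)) classifications <- fits$classifications
    fits <- fits$fits
  }
  stopIfNot(is(geometry, "ScanGeometry"), "'geometry' must be a ScanGeometry")
  dims <- c(geometry@nx, geometry@ny, geometry@nz)
  npix <- prod(dims)
  stopIfNot(length(fits) == npix,
            "one fit (or NULL) per grid pixel is required")
  val <- function() array(NA_real_, dims)
  shift <- val(); width <- val(); amp <- val(); npk <- val()
  mask <- array(TRUE, dims)
  for (p in seq_len(npix)) {
    f <- fits[[p]]
    if (is.null(f) || !converged(f) || nPeaks(f) == 0L) next
    k <- which.max(f@peaks@amplitude)
    shift[p] <- f@peaks@shiftGHz[k]
    width[p] <- f@peaks@fwhmGHz[k]
    amp[p] <- f@peaks@amplitude[k]
    npk[p] <- nPeaks(f)
    mask[p] <- FALSE
  }
  maps <- list(shift = shift, linewidth = width, amplitude = amp,
               n_peaks = npk)
  if (!is.na(dcLevel)) {
    stopIfNot(dcLevel > 0, "dcLevel must be > 0")
    maps$gain <- amp / dcLevel
  }
  if (!is.null(snr)) {
    sn <- val(); sn[!mask] <- snr[!mask]; maps$snr <- sn
  }
  if (!is.null(classifications))
    maps$metric <- multiPeakMetricMap(classifications, geometry, mask)
  new("BrillouinMaps", maps = maps, mask = mask, geometry = geometry)
}
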