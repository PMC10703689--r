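# Single- and multi-Lorentzian least-squares fitting of SBG spectra.
# The optimizer is Levenberg-Marquardt (minpack.lm::nls.lm) with analytic
# Jacobians; every model includes a constant baseline term for robustness to
# detrending residuals. Parameters are packed (A1, c1, w1, ..., Ak, ck, wk, b).

#' Zero-phase high-pass detrend of an acquisition stream
#'
#' Removes the DC component and slow drifts from the time-ordered,
#' concatenated acquisition stream with a zero-phase (forward-backward)
#' first-order Butterworth high-pass filter. Initial conditions assume the
#' first sample held indefinitely, so a constant stream maps to exactly zero.
#'
#' @param stream numeric samples in acquisition-time order.
#' @param sampleRateHz sampling rate (for a raster scan,
#'   nFreq / pixel time).
#' @param cutoffHz cutoff frequency, default 50 Hz (the inverse of a typical
#'   single-spectrum acquisition time); must be below the Nyquist frequency.
#' @return The filtered stream.
#' @export
detrendHighpass <- function(stream, sampleRateHz, cutoffHz = 50) {
  stopIfNot(cutoffHz > 0, "cutoffHz must be > 0")
  stopIfNot(sampleRateHz > 2 * cutoffHz,
            "cutoff must be below the Nyquist frequency (sampleRateHz / 2)")
  bf <- signal::butter(1, W = cutoffHz / (sampleRateHz / 2), type = "high")
  b <- bf$b; a <- bf$a
  # One causal pass of y[n] = b1 x[n] + b2 x[n-1] - a2 y[n-1]; pre-samples:
  # x held at x[1], y at the matching steady state (0 for a high-pass since
  # sum(b) = 0), so a constant stream maps to exactly zero.
  forward <- function(x) {
    n <- length(x)
    v <- b[1] * x + b[2] * c(x[1], x[-n])     # moving-average part
    as.numeric(stats::filter(v, filter = -a[2], method = "recursive", init = 0))
  }
  rev(forward(rev(forward(stream))))
}

# ---- internal fitting engine -------------------------------------------

lorModel <- function(theta, x, k) {
  y <- rep(theta[3 * k + 1], length(x))
  for (j in seq_len(k)) {
    A <- theta[3 * j - 2]; cc <- theta[3 * j - 1]; w <- theta[3 * j]
    u <- (x - cc) / (w / 2)
    y <- y + A / (1 + u^2)
  }
  y
}

lorJacobian <- function(theta, x, k) {
  J <- matrix(0, length(x), 3 * k + 1)
  for (j in seq_len(k)) {
    A <- theta[3 * j - 2]; cc <- theta[3 * j - 1]; w <- theta[3 * j]
    u <- (x - cc) / (w / 2)
    den <- 1 + u^2
    J[, 3 * j - 2] <- 1 / den
    J[, 3 * j - 1] <- A * 2 * u / ((w / 2) * den^2)
    J[, 3 * j] <- A * u^2 / (w / 2) / den^2   # d u/d w = -u/w => A*2u^2/(w den^2)/...
  }
  J[, 3 * k + 1] <- 1
  J
}

# Starting values for a single dominant peak from the smoothed spectrum.
peakInit <- function(x, y) {
  ys <- runningMean(y, 5L)
  base0 <- min(ys)
  imax <- which.max(ys)
  amp0 <- ys[imax] - base0
  c0 <- x[imax]
  above <- which(ys - base0 >= amp0 / 2)
  w0 <- if (length(above) >= 2) x[max(above)] - x[min(above)] else
    4 * mean(diff(x))
  list(amp = amp0, center = c0, width = max(w0, 2 * mean(diff(x))),
       base = base0, smoothed = ys)
}

fitEngine <- function(x, y, k, starts, lower, upper) {
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = starts,
    fn = function(p) lorModel(p, x, k) - y,
    jac = function(p) lorJacobian(p, x, k),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)))
  theta <- res$par
  ok <- res$info %in% c(1L, 2L, 3L, 4L) && all(is.finite(theta))
  n <- length(y); p <- length(theta)
  rss <- sum(res$fvec^2)
  se <- rep(NA_real_, p)
  if (ok && n > p) {
    J <- lorJacobian(theta, x, k)
    cv <- tryCatch(solve(crossprod(J)) * rss / (n - p), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  list(theta = theta, converged = ok, rms = sqrt(rss / n), se = se)
}

packFit <- function(eng, k, step) {
  th <- eng$theta
  A <- th[seq(1, by = 3, length.out = k)]
  cc <- th[seq(2, by = 3, length.out = k)]
  w <- th[seq(3, by = 3, length.out = k)]
  # ascending shift; ties broken by larger amplitude first
  o <- order(cc, -A)
  A <- A[o]; cc <- cc[o]; w <- w[o]
  se <- eng$se
  names(se) <- c(rbind(paste0("amplitude", seq_len(k)),
                       paste0("shift", seq_len(k)),
                       paste0("fwhm", seq_len(k))), "baseline")
  # degenerate decomposition: centers indistinguishable on the axis, or a
  # component that vanished (amplitude ~ 0 is unidentifiable in center/width)
  degen <- k >= 2 && (any(diff(cc) < step) ||
                      any(A <= 1e-6 * max(abs(A), 1e-300)))
  new("BrillouinFit",
      peaks = LorentzianPeaks(cc, w, pmax(A, 0)),
      baseline = th[3 * k + 1], stdErrors = se, residualRms = eng$rms,
      converged = eng$converged, degenerate = degen)
}

#' Fit a single Lorentzian to a spectrum
#'
#' Nonlinear least squares of one Lorentzian plus a constant baseline.
#' Initialization: center at the arg-max of the smoothed spectrum, FWHM from
#' the half-maximum crossings, amplitude from max-minus-baseline. Bounds:
#' the center within the axis range, the FWHM within [2 axis steps, axis
#' span]. When the initial amplitude estimate is below 3x the noise floor
#' (no significant peak), a non-converged result is returned rather than an
#' error.
#'
#' @param spectrum a \code{\link{BrillouinSpectrum}} with >= 5 points.
#' @return A \code{\link{BrillouinFit}}.
#' @examples
#' s <- makeSpectrum(makeFrequencyAxis(4, 6, 100), waterPeak())
#' peaks(fitLorentzian(s))
#' @export
fitLorentzian <- function(spectrum) {
  stopIfNot(is(spectrum, "BrillouinSpectrum"), "'spectrum' must be a BrillouinSpectrum")
  x <- spectrum@freqGHz; y <- spectrum@gain
  stopIfNot(length(x) >= 5L, "spectrum must have at least 5 points")
  step <- mean(diff(x)); span <- diff(range(x))
  ini <- peakInit(x, y)
  if (ini$amp <= 3 * noiseScale(y)) {
    return(new("BrillouinFit",
               peaks = LorentzianPeaks(ini$center, ini$width, max(ini$amp, 0)),
               baseline = ini$base,
               stdErrors = setNames(rep(NA_real_, 4),
                                    c("amplitude1", "shift1", "fwhm1", "baseline")),
               residualRms = sqrt(mean((y - mean(y))^2)),
               converged = FALSE, degenerate = FALSE))
  }
  rng <- max(y) - min(y)
  eng <- fitEngine(x, y, 1L,
                   starts = c(ini$amp, ini$center, ini$width, ini$base),
                   lower = c(0, min(x), 2 * step, min(y) - rng),
                   upper = c(3 * rng, max(x), span, max(y)))
  packFit(eng, 1L, step)
}

#' Fit a sum of two or three Lorentzians
#'
#' Sum-of-Lorentzians least squares with a constant baseline. Starting peaks
#' are the K largest local maxima of the smoothed spectrum that rise at
#' least 3x the noise floor above baseline; when fewer maxima exist, the
#' remaining starts fall back to an equal-spacing split across the dominant
#' peak's FWHM. Returned peaks are sorted by ascending shift (ties: larger
#' amplitude first); fits whose centers end up closer than one axis step are
#' flagged degenerate.
#'
#' @param spectrum a \code{\link{BrillouinSpectrum}}.
#' @param nPeaks 2 or 3.
#' @param minFwhmGHz physical lower bound on each fitted FWHM (GHz); default
#'   0.15, about the instrument spectral resolution. No real spectral feature
#'   can be narrower than the instrument lineshape; without this floor a
#'   surplus Lorentzian can collapse onto a single noise excursion.
#' @return A \code{\link{BrillouinFit}}.
#' @export
fitMultiLorentzian <- function(spectrum, nPeaks = 2L, minFwhmGHz = 0.15) {
  stopIfNot(is(spectrum, "BrillouinSpectrum"), "'spectrum' must be a BrillouinSpectrum")
  stopIfNot(nPeaks %in% c(2L, 3L), "nPeaks must be 2 or 3")
  k <- as.integer(nPeaks)
  x <- spectrum@freqGHz; y <- spectrum@gain
  stopIfNot(length(x) > 3L * k + 1L,
            "spectrum must have more points than fit parameters")
  step <- mean(diff(x)); span <- diff(range(x))
  ini <- peakInit(x, y)
  ys <- ini$smoothed
  sig <- noiseScale(y)
  if (ini$amp <= 3 * sig) {
    return(new("BrillouinFit",
               peaks = LorentzianPeaks(rep(ini$center, k), rep(ini$width, k),
                                       rep(max(ini$amp, 0) / k, k)),
               baseline = ini$base,
               stdErrors = rep(NA_real_, 3 * k + 1),
               residualRms = sqrt(mean((y - mean(y))^2)),
               converged = FALSE, degenerate = TRUE))
  }
  wlo <- max(2 * step, minFwhmGHz)
  w0 <- rep(max(ini$width / k, wlo), k)
  cand <- localMaxima(ys)
  cand <- cand[ys[cand] - ini$base >= 3 * sig]
  cand <- cand[order(ys[cand], decreasing = TRUE)]
  # merge maxima closer than half the dominant width (noise splits one peak
  # into several local maxima); highest wins
  minsep <- max(wlo, ini$width / 2)
  kept <- integer(0)
  for (ci in cand)
    if (!length(kept) || all(abs(x[ci] - x[kept]) >= minsep))
      kept <- c(kept, ci)
  cand <- kept
  # Multi-start: candidate start sets, best sum-of-squares wins.
  startSets <- list()
  if (length(cand) >= k) {
    top <- sort(cand[seq_len(k)])
    startSets <- c(startSets, list(list(
      centers = x[top], amps = pmax(ys[top] - ini$base, ini$amp / 10))))
  }
  # non-dominant maxima kept as starts, dominant peak split across its FWHM
  for (nOthers in seq.int(min(length(cand) - 1L, k - 1L), 0L)) {
    if (nOthers < 0L) next
    others <- if (nOthers > 0L) cand[1L + seq_len(nOthers)] else integer(0)
    nsplit <- k - nOthers
    splitC <- seq(ini$center - ini$width / 2, ini$center + ini$width / 2,
                  length.out = nsplit + 2L)[seq_len(nsplit) + 1L]
    startSets <- c(startSets, list(list(
      centers = c(splitC, x[others]),
      amps = c(rep(ini$amp / nsplit, nsplit),
               pmax(ys[others] - ini$base, ini$amp / 10)))))
  }
  rng <- max(y) - min(y)
  lower <- c(rbind(rep(0, k), rep(min(x), k), rep(wlo, k)), min(y) - rng)
  upper <- c(rbind(rep(3 * rng, k), rep(max(x), k), rep(span, k)), max(y))
  best <- NULL
  seen <- character(0)
  for (ss in startSets) {
    key <- paste(round(ss$centers, 3), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    eng <- fitEngine(x, y, k, c(rbind(ss$amps, ss$centers, w0), ini$base),
                     lower, upper)
    if (is.null(best) || (eng$converged && !best$converged) ||
        (eng$converged == best$converged && eng$rms < best$rms))
      best <- eng
  }
  packFit(best, k, step)
}

#' Brillouin gain from a fit
#'
#' G_B is the ratio between the fitted Lorentzian amplitude and the DC
#' component of the photodiode output, reported per fitted peak.
#'
#' @param fit a \code{\link{BrillouinFit}}.
#' @param dcLevel DC component, > 0.
#' @return Numeric vector of G_B values, one per peak.
#' @examples
#' s <- makeSpectrum(makeFrequencyAxis(4, 6, 100), waterPeak())
#' brillouinGain(fitLorentzian(s), dcLevel = 100)
#' @export
brillouinGain <- function(fit, dcLevel) {
  stopIfNot(is(fit, "BrillouinFit"), "'fit' must be a BrillouinFit")
  stopIfNot(length(dcLevel) == 1L && dcLevel > 0, "dcLevel must be > 0")
  amplitude(peaks(fit)) / dcLevel
}

#' Estimate the amplitude SNR of a spectrum
#'
#' SNR = fitted peak amplitude / standard deviation of the spectrum inside a
#' frequency window away from the Brillouin interaction (for water scans
#' typically 7-9 GHz). The window must be disjoint from every fitted peak
#' +/- 3 FWHM and contain at least 5 samples.
#'
#' @param spectrum a \code{\link{BrillouinSpectrum}} whose axis covers the
#'   noise window.
#' @param fit the \code{\link{BrillouinFit}} of the spectrum.
#' @param noiseWindow c(lo, hi) in GHz.
#' @return SNR of the highest-amplitude fitted peak. A zero noise estimate
#'   (noiseless spectrum) signals an error of class "sbsUnboundedSNR".
#' @export
estimateSNR <- function(spectrum, fit, noiseWindow = c(7, 9)) {
  stopIfNot(is(spectrum, "BrillouinSpectrum"), "'spectrum' must be a BrillouinSpectrum")
  stopIfNot(is(fit, "BrillouinFit"), "'fit' must be a BrillouinFit")
  stopIfNot(length(noiseWindow) == 2L && noiseWindow[1] < noiseWindow[2],
            "noiseWindow must be c(lo, hi) with lo < hi")
  pk <- peaks(fit)
  lo <- pk@shiftGHz - 3 * pk@fwhmGHz
  hi <- pk@shiftGHz + 3 * pk@fwhmGHz
  if (any(pmax(lo, noiseWindow[1]) < pmin(hi, noiseWindow[2])))
    stop("noise window overlaps a fitted peak +/- 3 FWHM")
  inWin <- spectrum@freqGHz >= noiseWindow[1] & spectrum@freqGHz <= noiseWindow[2]
  if (sum(inWin) < 5L)
    stop("fewer than 5 samples inside the noise window")
  noise <- sd(spectrum@gain[inWin])
  if (noise == 0)
    stop(structure(class = c("sbsUnboundedSNR", "error", "condition"),
                   list(message = "zero noise in window: SNR is unbounded",
                        call = sys.call())))
  max(amplitude(pk)) / noise
}
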