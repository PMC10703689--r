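# Independent oracles used across the suite. These deliberately avoid the
# package's fitting/classification code paths: the grid search enumerates
# (shift, fwhm) exhaustively with a linear solve for amplitude + baseline,
# and the crossing counter differentiates the sampled model numerically.

erfRef <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Exhaustive grid search for a single Lorentzian + constant baseline.
# Returns the best (shift, fwhm, amplitude, baseline) and its SSR.
gridSearchLorentzian <- function(x, y, shifts, fwhms) {
  best <- list(ssr = Inf)
  for (w in fwhms) {
    for (cc in shifts) {
      h <- 1 / (1 + ((x - cc) / (w / 2))^2)
      X <- cbind(h, 1)
      cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                     error = function(e) NULL)
      if (is.null(cf)) next
      r <- y - X %*% cf
      ssr <- sum(r^2)
      if (ssr < best$ssr)
        best <- list(ssr = ssr, shift = cc, fwhm = w,
                     amplitude = cf[1], baseline = cf[2])
    }
  }
  best
}

# Same grid search vectorized over many spectra (columns of Y); returns the
# maximum-likelihood (least-squares) shift per spectrum.
gridSearchShifts <- function(x, Y, shifts, fwhms) {
  nspec <- ncol(Y)
  bestSsr <- rep(Inf, nspec)
  bestShift <- rep(NA_real_, nspec)
  yss <- colSums(Y^2)
  for (w in fwhms) {
    for (cc in shifts) {
      h <- 1 / (1 + ((x - cc) / (w / 2))^2)
      X <- cbind(h, 1)
      XtX <- crossprod(X)
      XtY <- crossprod(X, Y)                       # 2 x nspec
      cf <- solve(XtX, XtY)
      ssr <- yss - colSums(XtY * cf)
      hit <- ssr < bestSsr
      bestSsr[hit] <- ssr[hit]
      bestShift[hit] <- cc
    }
  }
  bestShift
}

# Brute-force zero-crossing count: sample the sum-of-Lorentzians model on a
# dense grid, differentiate by central differences, normalize, offset, count
# sign changes away from the boundaries.
fdZeroCrossings <- function(peaks, offset, freqRange, nGrid = 1e4L) {
  x <- seq(freqRange[1], freqRange[2], length.out = nGrid)
  yv <- lorentzian(x, peaks)
  d <- (yv[c(-1, -2)] - yv[seq_len(nGrid - 2)]) / (x[3] - x[1])
  m <- max(abs(d))
  if (m == 0) return(0L)
  f <- d / m + offset
  s <- sign(f)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(0L)
  ch <- which(s[nz][-length(nz)] != s[nz][-1])
  pos <- (nz[ch] + nz[ch + 1]) / 2
  pos <- pos[pos > 2 & pos < length(f) - 1]
  length(pos)
}

# Numeric Cramer-Rao-style bound for the shift of a single Lorentzian +
# baseline model with iid Gaussian noise of sd sigma.
crlbShiftSd <- function(x, peak, sigma) {
  cc <- shiftGHz(peak); w <- fwhmGHz(peak); A <- amplitude(peak)
  u <- (x - cc) / (w / 2)
  den <- 1 + u^2
  J <- cbind(1 / den,                          # dA
             A * 2 * u / ((w / 2) * den^2),    # dc
             A * u^2 / (w / 2) / den^2,        # dw
             1)                                # baseline
  sqrt(solve(crossprod(J))[2, 2]) * sigma
}

waterAxis <- function() makeFrequencyAxis(4, 6, 100)
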