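#' Lorentzian Brillouin resonance
#'
#' Evaluate the Lorentzian lineshape
#' \deqn{L(\Omega) = A / (1 + ((\Omega - \Omega_B) / (\Gamma_B/2))^2)}
#' at the given frequencies. With several peaks the contributions are summed.
#'
#' @param freqGHz numeric vector of frequencies (GHz).
#' @param peak a \code{\link{LorentzianPeaks}} object (one or more peaks).
#' @return Numeric vector of gain values, one per frequency.
#' @examples
#' water <- LorentzianPeaks(5.00, 0.459, 1)
#' lorentzian(5.00, water)          # peak value 1
#' lorentzian(5.00 + 0.459/2, water)  # half maximum
#' @export
lorentzian <- function(freqGHz, peak) {
  stopIfNot(is(peak, "LorentzianPeaks"), "'peak' must be a LorentzianPeaks")
  validObject(peak)
  stopIfNot(all(peak@fwhmGHz > 0), "fwhmGHz must be > 0 for lineshape evaluation")
  out <- numeric(length(freqGHz))
  for (k in seq_len(length(peak))) {
    u <- (freqGHz - peak@shiftGHz[k]) / (peak@fwhmGHz[k] / 2)
    out <- out + peak@amplitude[k] / (1 + u^2)
  }
  out
}

# Analytic derivative dL/dOmega of a sum of Lorentzians (per GHz).
lorentzianDeriv <- function(freqGHz, peak) {
  out <- numeric(length(freqGHz))
  for (k in seq_len(length(peak))) {
    hw <- peak@fwhmGHz[k] / 2
    u <- (freqGHz - peak@shiftGHz[k]) / hw
    out <- out - 2 * peak@amplitude[k] * u / (hw * (1 + u^2)^2)
  }
  out
}

#' Stimulated Brillouin gain/loss spectrum
#'
#' The stimulated Brillouin gain (SBG) or loss (SBL) spectrum
#' \deqn{G(\Omega) = \pm \eta\, g(\Omega)\, l\, I_1}
#' where \eqn{g(\Omega)} is the (sum-of-)Lorentzian gain factor, \eqn{\eta}
#' the pump-probe overlap efficiency, \eqn{l} the interaction length and
#' \eqn{I_1} the pump intensity. The loss branch is the sign-flipped gain
#' branch of identical magnitude.
#'
#' @param freqGHz strictly increasing, non-empty frequency axis (GHz).
#' @param peaks a \code{\link{LorentzianPeaks}}.
#' @param model a \code{\link{GainModel}} (defaults to eta = l = I1 = 1).
#' @param sign \code{"gain"} (SBG, +) or \code{"loss"} (SBL, -).
#' @return Numeric vector of gain values on the axis.
#' @examples
#' ax <- makeFrequencyAxis(4, 6, 100)
#' g <- sbgSpectrum(ax, LorentzianPeaks(5, 0.459, 1))
#' @export
sbgSpectrum <- function(freqGHz, peaks, model = GainModel(),
                        sign = c("gain", "loss")) {
  sign <- match.arg(sign)
  stopIfNot(length(freqGHz) > 0, "frequency axis must be non-empty")
  stopIfNot(length(freqGHz) < 2 || all(diff(freqGHz) > 0),
            "frequency axis must be strictly increasing")
  validObject(model)
  s <- if (sign == "gain") 1 else -1
  s * model@eta * model@interactionLength * model@pumpIntensity *
    lorentzian(freqGHz, peaks)
}

#' Duty cycle of a pulsed scheme
#'
#' dc = pulse width x repetition rate. A width exceeding the period is an
#' error (never silently clipped to 1).
#'
#' @param x pulse width in ns (or a \code{\link{PulseScheme}}).
#' @param repRateMHz repetition rate in MHz.
#' @param ... unused.
#' @return Duty cycle as a fraction in (0, 1].
#' @examples
#' dutyCycle(40, 1.1)    # 0.044
#' dutyCycle(500, 1.0)   # 0.5
#' @export
setMethod("dutyCycle", "numeric", function(x, repRateMHz, ...) {
  stopIfNot(all(x > 0), "pulse width must be > 0")
  stopIfNot(all(repRateMHz > 0), "repetition rate must be > 0")
  dc <- x * 1e-9 * repRateMHz * 1e6
  if (any(dc > 1 + 1e-12))
    stop("pulse width exceeds the pulse period (duty cycle > 1)")
  pmin(dc, 1)
})

#' Pulse enhancement factor
#'
#' SNR enhancement of the pulsed pump-probe scheme over a CW scheme at equal
#' average powers: E = 1/dc. Monotone decreasing in the duty cycle, E = 1 in
#' the CW limit (dc = 1).
#'
#' @param x duty cycle in (0, 1] (or a \code{\link{PulseScheme}}).
#' @param ... unused.
#' @return Enhancement factor E >= 1.
#' @examples
#' enhancementFactor(0.044)  # ~22.7
#' enhancementFactor(1)      # CW limit
#' @export
setMethod("enhancementFactor", "numeric", function(x, ...) {
  stopIfNot(all(x > 0 & x <= 1 + 1e-12), "duty cycle must be in (0, 1]")
  1 / pmin(x, 1)
})

#' Equivalent CW pump power
#'
#' The CW pump power that yields the same SNR as the pulsed scheme at equal
#' average probe power: P_cw = P_avg x E = P_avg / dc.
#'
#' @param avgPumpMw average pump power (mW).
#' @param dc duty cycle in (0, 1].
#' @return Equivalent CW pump power in mW.
#' @examples
#' equivalentCWPump(13, 0.044)  # ~295 mW
#' @export
equivalentCWPump <- function(avgPumpMw, dc) {
  stopIfNot(all(avgPumpMw >= 0), "average pump power must be >= 0")
  avgPumpMw * enhancementFactor(dc)
}

#' Complex longitudinal modulus from a Brillouin resonance
#'
#' \deqn{M^* = \rho (\lambda_1 / 2n)^2 \Omega_B^2 (1 + i \Gamma_B/\Omega_B)}
#' with the shift and linewidth as ordinary frequencies. The storage modulus
#' is the real part, the loss modulus the imaginary part; their ratio equals
#' \eqn{\Gamma_B/\Omega_B} exactly.
#'
#' @param peak a single-peak \code{\link{LorentzianPeaks}} with positive shift.
#' @param optics a \code{\link{MaterialOptics}}.
#' @return A \code{\link{ComplexModulus}} (Pa).
#' @examples
#' m <- longitudinalModulus(LorentzianPeaks(5.07, 0.459, 1),
#'                          MaterialOptics(1.33, 1000, 780.24))
#' storagePa(m) / 1e9  # ~2.21 GPa
#' @export
longitudinalModulus <- function(peak, optics) {
  stopIfNot(is(peak, "LorentzianPeaks") && length(peak) == 1L,
            "'peak' must be a single LorentzianPeaks entry")
  validObject(optics)
  stopIfNot(peak@shiftGHz > 0, "Brillouin shift must be > 0")
  lam <- optics@pumpWavelengthNm * 1e-9          # m
  omega <- peak@shiftGHz * 1e9                   # Hz
  gamma <- peak@fwhmGHz * 1e9                    # Hz
  storage <- optics@massDensity * (lam / (2 * optics@refractiveIndex))^2 * omega^2
  ComplexModulus(storagePa = storage, lossPa = storage * gamma / omega)
}
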