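---
title: "Models and methods behind SBSmicro"
author: "SBSmicro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SBSmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SBSmicro)
```

# Scope

SBSmicro implements the computational pipeline of pulsed stimulated
Brillouin scattering (SBS) microscopy: the closed-form gain physics, a
synthetic-data generator that emulates shot-noise-limited acquisitions,
single- and multi-Lorentzian spectral fitting, the derivative-offset
single/multi-peak classifier, serpentine raster-scan reconstruction into
per-pixel Brillouin maps, and instrument metrology. This vignette explains
the models, the tunable parameters and the design decisions, in the order a
spectrum travels through the pipeline.

# The stimulated Brillouin gain model

Two counter-propagating beams (pump at $\omega_1$, probe at $\omega_2$)
interfere in the focal volume; when their frequency difference
$\Omega = \omega_1 - \omega_2$ matches an acoustic resonance, energy flows
from pump to probe (stimulated Brillouin gain, SBG) or vice versa (loss,
SBL). The measured spectrum is

$$G(\Omega) = \pm\, \eta\, g(\Omega)\, l\, I_1,$$

where $\eta$ is the pump-probe overlap efficiency, $l$ the interaction
length, $I_1$ the pump intensity, and $g(\Omega)$ a sum of Lorentzians

$$L(\Omega) = \frac{A}{1 + \left(\frac{\Omega - \Omega_B}{\Gamma_B/2}\right)^2},$$

with shift $\Omega_B$ (GHz), FWHM linewidth $\Gamma_B$ (GHz) and amplitude
$A$. Frequencies are carried in GHz everywhere in the package; $\eta$ and
$l$ are never quantified by the instrument alone, so `GainModel` defaults
all three scale factors to 1 and amplitudes are detector-referred. The SBL
branch is the sign-flipped SBG branch of identical magnitude.

The viscoelastic summary of a resonance is the complex longitudinal modulus

$$M^* = \rho \left(\frac{\lambda_1}{2n}\right)^2 \Omega_B^2
        \left(1 + i\,\frac{\Gamma_B}{\Omega_B}\right),$$

with $\Omega_B,\ \Gamma_B$ as ordinary frequencies (Hz inside the
conversion), $\rho$ the mass density, $n$ the refractive index and
$\lambda_1$ the pump wavelength. For water-like parameters
($n = 1.33$, $\rho = 1000\,$kg/m$^3$, $\lambda_1 = 780.24\,$nm,
$\Omega_B = 5.07\,$GHz) the storage modulus evaluates to about 2.21 GPa:

```{r}
m <- longitudinalModulus(LorentzianPeaks(5.07, 0.459, 1),
                         MaterialOptics(1.33, 1000, 780.24))
c(storage_GPa = storagePa(m) / 1e9, loss_over_storage = lossPa(m) / storagePa(m))
```

Note the formula uses ordinary frequency, not angular frequency; an
angular-frequency reading would inflate the modulus by $(2\pi)^2$ and is
inconsistent with the value above.

## Pulsed-scheme arithmetic

With pulse width $T_\mathrm{pulse}$ and period $T_\mathrm{period}$, the duty
cycle is $\mathrm{dc} = T_\mathrm{pulse}/T_\mathrm{period}$. At fixed
*average* powers, pulsing concentrates both beams into the same on-time, so
the pump-probe product grows as $1/\mathrm{dc}$ while the (probe-limited)
noise is unchanged: the SNR enhancement is $E = 1/\mathrm{dc}$, and a pulsed
scheme with average pump power $P$ matches a CW scheme with pump
$P/\mathrm{dc}$. A width exceeding the period is a hard error, never clipped.

```{r}
ps <- PulseScheme(pulseWidthNs = 40, repRateMHz = 1.1, avgPumpMw = 13)
c(dc = dutyCycle(ps), E = enhancementFactor(ps),
  cw_equiv_mW = equivalentCWPump(13, dutyCycle(ps)))
```

# The synthetic-data generator

The generator is the package's stand-in for the instrument and defines the
conditions under which everything downstream is tested.

* **Noise model.** Additive i.i.d. Gaussian noise with standard deviation
  $\sigma = A_\mathrm{max}/\mathrm{SNR}$, referenced to the largest peak
  amplitude. This matches how the instrument's SNR is defined (peak
  amplitude over the off-resonance standard deviation) and is homoscedastic
  across the axis. No Poisson simulation: the detector operates in a regime
  where the lock-in output noise is well described as Gaussian.
* **Time scaling.** The SNR is specified at a reference integration time
  (20 ms by default); other times scale $\sigma \propto t^{-1/2}$, the
  shot-noise limit. This is an assumption of the generator, made so that
  precision-scaling analyses have a known ground truth.
* **Default water resonance.** 5.00 GHz shift, 0.459 GHz FWHM on a
  4–6 GHz, 100-point axis — the measured water linewidth at 20 ms
  integration and the instrument's standard water scan. Default SNR for
  water-like simulations is 38, a typical per-plane average in cell
  imaging.
* **Phantoms.** `makePhantom()` builds labeled grids with the documented
  material resonances: a PDMS bead (4.07 GHz) in agarose (5.12 GHz), an
  oil (7.04 GHz)/glass axial edge where the glass resonance lies outside
  the scanned range, uniform water, and a two-layer phantom with an
  overlap stripe carrying both resonances for classifier maps. Linewidths
  for PDMS (0.35 GHz), agarose (0.40 GHz) and oil (0.50 GHz) are chosen
  once as plausible instrument-broadened values; only the shifts matter to
  the tests that use these phantoms.
* **Raster streams.** `makeScanStream()` serializes a phantom the way the
  stage acquires it: frequency fastest, serpentine fast axis (every second
  line reversed, parity counted from line 0), alternate z-planes traversed
  in reversed row order, and — when a stage delay is configured — the
  content of every second line displaced by
  `round(stageDelayMs / pixelTimeMs)` pixels along the travel direction
  (100 ms delay at 20 ms pixel time = 5 pixels). Seeds are explicit
  arguments; no global RNG state is touched.

What the generator does **not** emulate: optical point-spread-function
blur (resolution is tested on erf edge profiles, not image simulation),
refractive-index-mismatch aberrations, drift beyond the fixed line shift,
or structured (non-white) noise. Passing tests therefore demonstrate
correctness of the analysis pipeline under the stated noise model, not
performance on every artifact real hardware can produce.

# Spectral fitting

Streams are optionally detrended with a zero-phase (forward–backward)
first-order Butterworth high-pass at 50 Hz — the inverse of a typical
single-spectrum time — applied along acquisition time. Zero phase avoids
biasing peak centers; initial conditions assume the first sample held
indefinitely, so a constant stream maps to exactly zero. Because some
baseline always survives filtering (or filtering is off), every fit model
includes a constant baseline term.

Fits are Levenberg–Marquardt least squares with analytic Jacobians.
Initialization is data-driven: the center starts at the arg-max of the
5-point running-mean smoothed spectrum, the FWHM at the half-maximum
crossing width, the amplitude at max-minus-baseline. Bounds keep the center
inside the axis and the FWHM inside [2 axis steps, axis span]. A spectrum
whose initial amplitude estimate is below 3x the noise floor (estimated
robustly from first differences) returns a non-converged result instead of
an error — a flat or signal-free pixel is data, not a bug.

## Multi-peak fitting

`fitMultiLorentzian()` fits sums of 2 or 3 Lorentzians. Three design
choices matter:

* **Starting values.** Candidate peaks are local maxima of the smoothed
  spectrum at least 3x the noise floor above baseline, merged so that no
  two candidates are closer than half the dominant width (noise splits one
  peak into several nearby maxima). When fewer candidates than components
  exist, the dominant peak is split evenly across its FWHM. Several start
  sets (all-candidates, candidates-plus-split, pure split) are run and the
  lowest sum of squares wins; multi-start costs little and rescues fits
  where an overlapping doublet hides behind a single smoothed maximum.
* **FWHM floor (default 0.15 GHz).** No real spectral feature can be
  narrower than the instrument lineshape (~150 MHz spectral resolution).
  Without this physical floor, the surplus Lorentzian reliably collapses
  onto a single noise excursion (width at the numerical floor, amplitude a
  few noise sigmas), corrupting the classifier. The single-peak fit keeps
  the purely numerical 2-step bound: with one component there is nothing
  to collapse.
* **Ordering and degeneracy.** Peaks return sorted by ascending shift
  (ties: larger amplitude first). A decomposition is flagged degenerate
  when two centers fall within one axis step or a component's amplitude
  vanishes — in either case the extra component is unidentifiable.

Per-pixel gain is $G_B = A/\mathrm{DC}$, the fitted amplitude over the
photodiode DC level. The SNR estimate divides the fitted amplitude by the
standard deviation inside a user-chosen off-resonance window (7–9 GHz for
the standard water scan; the window is configurable because scan ranges
vary), refusing windows that touch any fitted peak ±3 FWHM.

# The single/multi-peak classifier

To distinguish an asymmetric single resonance from genuinely multiple
mechanical components, the classifier fits the two-Lorentzian model,
computes its *analytic* derivative on a dense grid, normalizes by the
maximum absolute value, adds an offset, and counts zero crossings:

* a unimodal lineshape crosses zero exactly once at zero offset, and
  exactly twice at any non-zero offset in (−1, 1) — the normalized
  derivative returns to zero in both tails, so the offset line is crossed
  once on each side of the extremum;
* a second maximum adds two crossings at zero offset;
* a shoulder ("bump") that does not create a second maximum still ripples
  the derivative, and some offset in the sweep reveals extra crossings.

The offset sweep uses 21 evenly spaced values in [−0.5, +0.5] of the
normalized derivative (the normalization makes this range scale-free; the
spectrum's amplitude cancels). Crossings within one grid step of the axis
boundary are ignored as finite-range edge effects. The label is "multi"
when any offset produces more crossings than the unimodal expectation, and
the **multi-peak metric** is the fraction of offsets that do — an artifact
convention chosen here because the per-pixel multi-peak quantity is
rendered as an image and a [0, 1] fraction is directly interpretable;
single-peak pixels are exactly 0.

One screen precedes the test: only fitted components whose amplitude is
significant against the spectrum's noise floor enter the derivative
evaluation. The threshold is $z_{\alpha/m}\,\hat\sigma$ with a design
false-positive rate $\alpha = 0.001$ (the documented rate at which pure
water spectra may be mislabeled "multi") Bonferroni-corrected over the
$m$ spectral resolution elements in the scan range. Without this screen
the two-Lorentzian fit's surplus component — which the optimizer happily
parks on the largest noise excursion — would fire the bump detector on a
large fraction of pure single-peak spectra, which contradicts the
instrument's documented behavior. With it, 10,000 simulated water spectra
at SNR 38 classify ≥ 99.9% single while clearly separated doublets at the
same SNR are detected essentially always.

```{r}
ax <- makeFrequencyAxis(4, 7, 150)
double <- makeSpectrum(ax, LorentzianPeaks(c(5.03, 5.8), 0.46, c(1, 0.8)),
                       snr = 38, seed = 1)
classifySpectrum(double)
```

# Scan reconstruction

Reconstruction inverts the generator exactly: reshape the stream to
[frequency × pixels], permute pixels from acquisition order to grid order
(undoing serpentine and plane flips), then shift every second line back by
`round(stageDelayMs / pixelTimeMs)` pixels. Three conventions are fixed for
determinism where the acquisition itself does not dictate them: pixel
coordinates are counted from 0 with x the fast axis; line parity is counted
from line 0 in acquisition order; the shift direction defaults to the
travel direction (+x on even lines) and is configurable because it depends
on stage hardware. Vacated pixels are **masked, never wrapped or
interpolated** — wrapping would fabricate data. Reconstruction is a pure
permutation plus masking: every surviving sample equals a stream sample
exactly, and on noiseless input the full
generator → reconstruction → fitting roundtrip reproduces the phantom's
shift and linewidth to better than $10^{-6}$ GHz on every unmasked pixel.

Maps are assembled per quantity (shift, linewidth, amplitude, gain, SNR,
peak count, multi-peak metric) in phantom coordinates. Multi-peak pixels
contribute their highest-amplitude peak to the scalar maps; the full peak
table stays in the fit results.

# Metrology

* **Axis calibration** subtracts the differential frequency — the shift of
  one material measured under fast versus slow scanning — from the axis.
* **Spectral resolution** is the measured reference linewidth minus its
  intrinsic (low-NA) linewidth; the reference water FWHM defaults to
  308 MHz. The subtraction is used as stated by the convention, with no
  deconvolution claim: 459.2 MHz at 20 ms gives 151 MHz, 410 MHz at 40 ms
  gives 102 MHz.
* **Precision curves** fit every spectrum of a repeated-acquisition series
  and report the per-time standard deviation of shift and linewidth;
  `precisionSlope()` is the unweighted least-squares slope of
  $\log_{10}\sigma$ versus $\log_{10} t$ (weighting is unstated in the
  underlying protocol, and with equal repeats per time the unweighted fit
  is the natural choice). Shot-noise-limited data give −0.5.
* **Edge resolution** fits
  $\mathrm{offset} + \mathrm{scale}\cdot\mathrm{erf}\!\left((x - x_0)/(\sigma\sqrt2)\right)$
  to an amplitude profile across a material edge and reports
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. Profiles without a dominant
  monotone trend (|Spearman ρ| < 0.2) are flagged non-converged.
* **Scan-range study**: Monte-Carlo bias and scatter of the fitted shift
  and linewidth versus spectral scan range, at a *fixed frequency step*
  (0.02 GHz by default). Holding the step — rather than the point count —
  fixed isolates the effect of the range itself; with a fixed point count a
  wider range simply dilutes the sampling of the peak and scatter grows as
  $\sqrt{\mathrm{range}}$, which says nothing about range-dependent
  fidelity. At fixed step, ranges beyond ~2 GHz neither help nor hurt.

# Numerical choices and problem sizes

Tolerances and sizes used by the test suite and the acceptance script, all
chosen as round, comfortable values for the statistics involved: noiseless
recovery is asserted at $10^{-6}$ (single fit) and $10^{-4}$ (multi fit)
relative error; the precision-slope simulation uses 300 repeats at each of
5 times (5–80 ms, factor-2 spaced); the classifier operating point uses
10,000 water spectra; Monte-Carlo tolerances (15–20%) follow from the
sampling error of a standard deviation over the repeat counts used. The
dense derivative grid uses 2001 points; the brute-force cross-checks use
$10^4$. Scan phantoms in tests are tens of pixels per side — large enough
to exercise serpentine parity, plane flips and line shifts in both parities,
small enough to fit everything comfortably in a routine test run.

# Known limitations

* The absolute gain calibration ($\eta$, $l$, $I_1$) is user-supplied;
  without it, amplitudes and $G_B$ are detector-referred numbers.
* The classifier decides 1-versus-2 components; 3-peak fits are
  user-invoked, and no information-criterion model selection is attempted.
* The linewidth-subtraction convention for spectral resolution is exactly
  that — a convention; it is not a deconvolution.
* The generator's idealizations (white Gaussian noise, no PSF, rigid
  serpentine timing) bound what green tests prove about real acquisitions.
* Measured biological images, measured SNR values and measured optical
  resolutions from real instruments are outside what synthetic data can
  certify; the package covers them with parameter-recovery surrogates.
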