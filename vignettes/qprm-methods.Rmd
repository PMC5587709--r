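---
title: "Quantum probe relaxation microscopy: models and design choices"
author: "qprm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum probe relaxation microscopy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qprm)
```

## The measurement this package models

Nitrogen-vacancy (NV) centres in diamond are point defects with a
spin-1 ground state that can be polarised and read out optically at
room temperature. An array of NV centres a few nanometres below the
diamond surface acts as a camera-resolved grid of magnetometers: the
spin-lattice relaxation time $T_1$ of each probe shortens when magnetic
noise in its environment has spectral weight at the probe's transition
frequency. Because that transition is field-tunable through the Zeeman
effect, sweeping a static field $B_0$ and mapping the relaxation rate
$\Gamma_1 = 1/T_1$ per pixel amounts to electron paramagnetic resonance
spectroscopy with optical, diffraction-limited readout — here of
hexaaqua-Cu$^{2+}$ ions in solution above the diamond chip.

The package implements the full analysis chain for such an experiment
and, since no raw data are deposited anywhere, a seeded generator of
every input the chain consumes.

## Spin physics

The probe transition used throughout is $|0\rangle \to |-1\rangle$,
with frequency $D - \gamma_{NV} B_0$ ($D = 2.87$ GHz,
$\gamma_{NV} = g_{NV}\,\mu_B/h$, $g_{NV} = 2.0028$). A spin-1/2 target
with effective g-factor $g$ has transition frequency
$g\,(\mu_B/h)\,B_0$; the two cross at

$$B_{\mathrm{res}} = \frac{hD}{(g_{NV} + g)\,\mu_B},$$

which is 512.0 G for free electrons ($g = 2.0023$) and 488.0 G for
hexaaqua-Cu$^{2+}$, whose axial tensor ($g_\parallel = 2.400$,
$g_\perp = 2.099$) motionally averages in solution to
$\langle g \rangle = (g_\parallel + 2 g_\perp)/3 = 2.199$.

The probe responds to environmental noise at angular frequency
$\omega_E$ through a Lorentzian filter of half-width $\Gamma_2$
(the transverse relaxation rate) centred on its own transition; the
relaxation rate is the overlap integral of this filter with the
environment's spectral density. For a Lorentzian bath of width $R$ the
integral has the closed form

$$\Gamma_1(B_0) = \frac{b^2}{2}\,
  \frac{\Gamma_2 + R}{(\Gamma_2 + R)^2 +
  \left(2\pi D - (\gamma_{NV} + \gamma_{T}) B_0\right)^2},$$

because the convolution of two Lorentzians adds their widths. Both
routes are implemented (`filterFunction()` + numerical quadrature, and
`targetSpectrum()`), and their equivalence is a test, not an
assumption. Since $\Gamma_2 \approx 2.5\times10^7$ rad/s is tiny
against the Cu$^{2+}$ width $R \approx 1.8\times10^9$ rad/s, the
measured spectrum is essentially the bath spectral density itself and
deconvolution is unnecessary; the tests quantify this (fitted $R$ with
and without the convolution differ by far less than 2%).

**Unit conventions.** All spectral quantities are angular frequencies
(rad s$^{-1}$); gyromagnetic ratios are $2\pi g \mu_B/h$ in
rad s$^{-1}$ G$^{-1}$; fields are in gauss at every API surface; $D$ is
in Hz. One convention had to be imposed because the spectrum model
mixes $2\pi D$ with $\gamma B_0$ terms. $\Gamma_2$ is taken as
$2\pi \times$ (ODMR linewidth in Hz) $= 2\pi \cdot 4\,\mathrm{MHz}
= 2.51\times 10^7$ rad/s; this conflates the inhomogeneous ODMR width
with the filter width, which is the convention of the experiment being
modelled. Only the $|0\rangle\to|-1\rangle$ probe branch and the
$|-\tfrac12\rangle \to |+\tfrac12\rangle$ target branch enter the
resonance matching; other NV orientations are assumed deselected by
the microwave pulse, and everything stays below the ground-state
anti-crossing at 1024 G.

## The synthetic-data generator

The generator emulates the study conditions of the experiment:

* **Masks** (`makeMask()`): uniform fields, coarse block letters, or
  gratings (default 500 nm lines at 1 µm pitch) of a reference
  concentration, default 100 mM.
* **Ground truth** (`truthFromMask()`): per pixel,
  $\Gamma_1 = \Gamma_{\mathrm{base}} + \Gamma_1^{(I)} +
  \Gamma_1^{(T)}$. The base rate defaults to $1/730\,\mu s$ (the
  off-resonance rate of the array with analyte present). The intrinsic
  surface-spin bath is centred at 511.3 G (the calibration peak field,
  i.e. $g = 2.0077$ by exact inversion) with total width
  $\Gamma_2 + R_{\mathrm{int}} = 60.4\times10^6$ rad/s and a coupling
  set for an on-resonance intrinsic rate of $\approx 2500$ s$^{-1}$
  (no amplitude is published; this is a generator choice of realistic
  size). The target coupling scales linearly with local concentration
  through $b^2 = 2C/(4.35\times10^{10}\,h^3)$, the relation that makes
  the closed-form spectrum consistent with the concentration
  estimator below. A linear field gradient (defaults 0.07% in x, 0.4%
  in y across the FOV) perturbs per-pixel fields.
* **Decay stacks** (`simulateDecayStack()`): the expected per-cycle
  signal per pixel is
  $n_{ph}\,[(1-c) + c\,e^{-(\tau/T_1)^p}] + \mathrm{offset}$ with
  optical contrast $c = 0.04$; the image is blurred by a Gaussian PSF
  (default $\sigma = 305/2.3548 \approx 130$ nm, i.e. the 305 nm
  diffraction limit read as a FWHM) with an exactly normalised kernel,
  then counts are drawn Poisson after scaling by the cycle number
  (default $N_c = 10{,}000$). The stretched exponential is *decaying*;
  the growing form that appears in print cannot describe relaxation
  and is treated as a typo. The photon budget (default 300
  photons/pixel/cycle) is not published; it was chosen once so that
  fitted $T_1$ uncertainties at $N_c = 10^4$ sit at the percent scale
  of the reported error bars.
* **Kinetics** (`simulateKinetics()`): the redox scheme
  2Cu$^{2+}$ + AH$_2 \leftrightarrow$ 2Cu$^+$ + A + 2H$^+$ is modelled
  as a termolecular forward step ($k_f$, default 0.8 L$^2$ mol$^{-2}$
  s$^{-1}$) with irreversible consumption of the ascorbate and a
  first-order reoxidation of Cu$^+$ ($k_{ox}$, default
  $2\times10^{-3}$ s$^{-1}$) that lumps disproportionation and aerobic
  oxidation. A closed 1-D rate law cannot dip and recover (autonomous
  scalar ODEs are monotone), so the reductant carries its own ODE;
  copper mass balance is exact. The defaults were fixed by a one-time
  scan of the ODE alone so that $\approx 60\%$ of the Cu$^{2+}$ is
  reduced 500 s after mixing with full recovery by 4000 s — the
  calibration the simulated experiment is defined by. The tiny
  equilibrium constant ($K_e = 5\times10^{-9}$ M$^2$) is carried as
  configuration: it places equilibrium almost fully on the Cu$^{2+}$
  side, consistent with full long-time recovery. Expected two-point
  intensities are linear in the rate change about the baseline
  (the printed two-point estimator, inverted), with band-limited
  multiplicative laser noise (default 0.1%, moving-average filtered —
  the published traces show oscillations of unspecified form) and
  Poisson shot noise on both time points.

Every generator is a pure function of (configuration, seed); sweeps
derive per-field seeds as `seed + i - 1`, so runs are bit-reproducible.

**What the generator does not emulate:** optical sectioning, camera
read noise beyond a constant offset, NV charge-state dynamics,
microwave pulse errors, drift, and any spatial correlation of the
surface-spin bath. Passing tests therefore demonstrate correctness of
the analysis chain under the stated noise model, not robustness to
every artefact of real hardware.

## Relaxometry

`fitDecay()` fits $y = A e^{-(\tau/T_1)^p} + c$ by weighted
Levenberg-Marquardt. Initialisation: $c_0$ from the mean of the last
decile, $A_0 = y_1 - c_0$, $T_1$ from the interpolated $1/e$ crossing,
$p_0 = 1$; $p$ is bounded to $[0.3, 2]$. Amplitude and offset are
always free. Weights are Poisson ($\sigma^2 = $ counts) for raw count
data and uniform for pre-normalised data; the Poisson weights are
capped at a $10^3$ dynamic range so nearly-empty tail bins cannot
dominate. The LM implementation occasionally rejects a near-collinear
initial Jacobian outright, so the fit uses a three-point multi-start
and a bounded `port` fallback; a still-failing curve is retried once
as a single exponential ($p = 1$) and finally flagged rather than
thrown, and flagged pixels are excluded from all aggregates. FOV and
ROI curves are fit on *summed* counts (summing and averaging differ
only by a scale absorbed in $A$ and $c$).

## Spectroscopy

`buildSpectrum()` converts per-field $T_1$ fits to
$\Gamma_1 = 1/T_1$ with $\sigma_\Gamma = \sigma_{T_1}/T_1^2$, merging
duplicate fields by inverse variance. `subtractCalibration()`
implements the two-measurement scheme: the target spectrum is the
combined (intrinsic + target) spectrum minus the target-free
calibration, linearly interpolated in field with no extrapolation and
added variances. `fitTargetSpectrum()` fits the closed form with free
$(b^2, R, g)$; $\Gamma_2$ is held fixed because only the sum
$\Gamma_2 + R$ enters the lineshape and the pair would be degenerate.
When the analyte concentration is known, the probe depth follows from
the fitted coupling, $h = (2C/(4.35\times10^{10} b^2))^{1/3}$. Whether
the printed estimator constant intends $h$ in metres or nanometres is
not stated; the metre convention is adopted, so absolute $h$ and $C$
values are order-of-magnitude (the dimensionless shape parameters
$g$ and $R$, and all *relative* concentrations, are unaffected).
Per-pixel g maps (`perPixelGMap()`) fit only $g$ and amplitude per
pixel, sharing the FOV-fitted width to stabilise low-SNR pixels;
pixels whose peak does not exceed three sigma, or whose fit fails, are
excluded from the reported mean and SD.

## Quantification

`concentrationFromRate()` implements
$C = 4.35\times10^{10}\,\Gamma_1\,h^3\,(\Gamma_2 + R)$ mol/L — the
printed expression carries $(\Gamma_2+R)^2/(\Gamma_2+R)$, which is
algebraically collapsed. The default sensing voxel is
$1.6 \times 1.6 \times 0.01\ \mu m^3$; its volume is reported at full
precision ($0.0256\ \mu m^3$ = 25.6 aL; commonly rounded to 25 aL).
The detection limit is the concentration whose on-resonance rate
equals the rate uncertainty, converted to spins and moles per voxel.

## Two-point kinetics

The two-point estimator
$\Gamma_1 = (\Delta I/\Delta I_0)/(c\,\tau_{sp})$ is linear and
accurate to first order in $\Gamma_1 \tau_{sp}$; the reference level
$\Delta I_0$ is the mean normalised intensity over a user-set
pre-reaction baseline window (no reference window is published;
everything before the reaction start is used). Reduction of the
spin-active pool slows relaxation and *raises* the probe-point
intensity; this sign convention is covered by a directional test. The
FOV-integrated intensity is used for the reduction-fraction figure
(the per-voxel alternative is not distinguishable in print).
`fitRedoxModel()` fits the generator ODE to a concentration series by
least squares in the log of the rate constants.

## Resolution analysis

`lineProfile()` samples images by bilinear interpolation with
perpendicular averaging; `fitGaussianPeaks()` fits a sum of Gaussians
plus a constant baseline, seeding peaks at local maxima exceeding
baseline + 3 MAD when centres are not supplied, with the width bounded
below by half the sample spacing (narrower peaks are unresolvable and
the bound prevents degenerate collapse). The printed line-cut widths
are treated as Gaussian $\sigma$, not FWHM (the print is ambiguous).
A fitted width depends strongly on the fit window and on whether
neighbouring grating lines are modelled: the package protocol crops
the profile to exactly the modelled peaks and fits them jointly with a
shared baseline, and the oracle used in tests applies the *same*
protocol to a directly convolved boxcar-grating profile. Under this
protocol a 500 nm line at 1 µm pitch blurred at the 305 nm diffraction
limit fits at $\sigma \approx 210$ nm — noticeably below the
published $290 \pm 30$ nm line-cut width, which evidently contains
broadening beyond ideal diffraction plus geometry. The corresponding
acceptance check against the printed band is left failing rather than
re-tuned, with the oracle-consistency check as the primary assertion.

## Problem sizes and numerical choices

The simulated experiments used by the tests and the pipeline default
to small fields of view (8-16 px square, 0.4 µm pixels), 18
log-spaced evolution times from 1 µs to 3 ms, 17-field sweeps over
400-560 G, and 10,000 cycles — small enough that the full suite runs
in well under a minute while keeping shot noise at the measurement
scale. Calibration sweeps add fine sampling (0.75 G) around the
narrow 511.3 G surface-spin peak, whose width in field
($\approx 1.7$ G) would otherwise be unresolved; note that the default
0.4% field gradient inhomogeneously broadens the FOV-summed intrinsic
line, so width-recovery tests disable the gradient. ODE integration
uses `deSolve::ode` (lsoda) at rtol $10^{-9}$; integrals over
Lorentzians are computed in units of the linewidth so adaptive
quadrature sees an O(1) peak. TIFF stacks are written as 32-bit float
pages normalised by a scale factor stored in the JSON sidecar.

## Known limitations

Absolute concentrations and probe depths inherit the unit ambiguity of
the printed estimator constant (order of magnitude only). The
intrinsic-bath amplitude and the photon budget are generator choices,
not published quantities. The per-pixel g-map spread reported by the
simulator is narrower than the published histograms because the
generator contains no pixel-to-pixel variation of the surface bath.
Multi-species spectral unmixing, anisotropic (powder-pattern)
lineshapes, bi-exponential or rate-distribution relaxation models, and
instrument control are out of scope.
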