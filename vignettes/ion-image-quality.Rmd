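---
title: "Modelling image quality in energy-loss ion CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling image quality in energy-loss ion CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionct)
```

`ionct` models the electromagnetic physics that bounds image quality in
energy-loss ion imaging: a beam of ions crosses a 20 cm water cylinder, each
particle's energy loss is converted to a water-equivalent thickness (WET),
and the WET line integrals are reconstructed into a relative-stopping-power
map. This vignette records the model, its assumptions, the parameter
defaults and the design choices that were genuinely open.

## Transport model

Kinetic energies are stored per nucleon (MeV/u) everywhere; whole-ion
quantities (`pv`, stopping power, energy variances) are formed only inside
the kernels that need them. The stopping power is the uncorrected
Bethe–Bloch form

$$S(E) = \frac{Z^2 K}{\beta^2}\left[\ln\!\left(\frac{2m_ec^2}{I}
\frac{\beta^2}{1-\beta^2}\right) - \beta^2\right],$$

with $K = 0.170$ MeV/cm for water (the standard coefficient
$0.307\,\mathrm{MeV\,cm^2\,g^{-1}}$ times water's $Z/A = 0.5551$ and unit
density). Shell and density-effect corrections are omitted; consequently a
validity floor of 1 MeV/u is enforced and results above ~500 MeV/u
slightly underestimate the range. The mean excitation energy defaults to
$I = 78$ eV, the value used by modern condensed-history transport codes for
water; moving between 75 and 78 eV shifts ranges by about 1%, which is the
scale of the residual difference between the computed 350 MeV proton range
(66.8 cm) and the published 66.2 cm.

Ranges come from adaptive quadrature of $1/S$ (the ~0.02 mm of residual
range below the floor is neglected); depth–energy transport uses a
fixed-step RK4 march with a 0.1 mm step; profile tables default to a 0.5 mm
grid. `energy_for_range()` inverts the range integral with a bracketed root
solve to better than 0.1 MeV/u.

## Scattering and the constrained envelope

Multiple Coulomb scattering is treated as a Gaussian process with scattering
power $T(u) = f^2 Z^2 E_0^2 / (pv(u)^2 X_0)$, $E_0 = 13.6$ MeV/c,
$X_0 = 360.8$ mm (water, constant — the phantom is uniform), and
$f = 1 + c\,\ln(\ell/X_0)$ the logarithmic thickness correction, clamped at
zero for sub-millimetre paths. The coefficient defaults to $c = 1/9$;
the classical Highland value 0.038 is available through
`log_coefficient` and changes the 20 cm proton envelope by about +5%.
Moments use the kernel $(x-u)^n$ — the distance from the evaluation depth —
which is the form that makes the position variance equal the lateral spread
a simulation actually shows at that depth.

The spatial-resolution metric needs the lateral uncertainty of a particle's
path *given* its boundary measurements. The choice of conditioning is a real
modelling decision:

* conditioning on the entry vector and the measured **exit position**
  (default, `conditioning = "exit_position"`) describes a reconstruction
  that bins particles by measured entry and exit points; for 200 MeV
  protons through 20 cm it gives $\sigma_{mid} = 0.614$ mm, i.e.
  MTF\(_{10\%}\) = 5.6 lp/cm;
* conditioning additionally on the **exit direction**
  (`"exit_vector"`, maximum-likelihood-path style) narrows the envelope to
  0.50 mm (6.8 lp/cm).

The exit-position form reproduces both the published proton resolution
(5.73 lp/cm) and the package's own Monte Carlo binned the same way, and is
therefore the default; the logarithmic factor is evaluated once for the
full traversed thickness so that the analytic envelope and the step-by-step
Monte Carlo accumulate the same total variance. The envelope is *not*
symmetric about mid-depth: the beam slows down, late segments scatter more,
and the peak sits ~7% of the thickness downstream of the mid-plane (about
15% asymmetry point-by-point for protons). The MTF uses the mid-depth
value — the reconstruction point of the central voxel — which lies within
10% of the peak.

Path sampling for the energy-loss expectation uses scaled-envelope curves:
path $p$ follows $y(x) = z_p\,\sigma(x)$ with $z_p$ the Gaussian quantile,
65 equally weighted quantiles by default (the 65→129 refinement changes the
expected loss by <1%). This preserves the envelope exactly and is all the
noise model needs, at the price of ignoring path-shape variability within a
quantile.

## Straggling and WET noise

Energy-loss straggling follows the Tschalär solution
$\sigma^2(E_{out}) = k_1^2(E_{out})\int k_2/k_1^3\,dE$ integrated over
whole-ion energy. The straggling power is implemented as
$k_2 = Z^2 K m_ec^2\,\eta_e\,(1-\beta^2/2)/(1-\beta^2)$ per unit length:
the electron-mass factor is absorbed so that the non-relativistic
unit-charge limit reproduces the Bohr value 0.0871 MeV²/cm for water, and
the charge exponent is quadratic — the published per-ion noise ladder
(helium/proton WET noise = 1.26/2.52 = 0.50) pins $Z^2$, since a linear
charge dependence would predict 0.35. Scattering adds energy noise through
the path ensemble, $\sigma^2_{MCS} = E[\Delta E^2]-E[\Delta E]^2$; the two
are independent and add in quadrature, and WET noise follows as
$\sigma_{WET} = \sigma_E/S(E_{out})$, evaluated at the phantom exit.

The analytic WET noise sits 5–9% above the published condensed-history
Monte Carlo values for all five ions (2.65 vs 2.52 mm for protons, 1.33 vs
1.26 mm for helium): the Gaussian Bohr–Tschalär kernel is slightly hotter
than the Urban ionisation-fluctuation model those values were measured
with. The deviation is systematic and documented rather than calibrated
away.

## Figures of merit

SNR and central-voxel dose implement the uniform-cylinder relations
directly; both are exact scaling laws ($\mathrm{SNR}\propto a\sqrt{MN_D}$,
$D_c \propto \mathrm{SNR}^2 a^{-4}$) once the physics inputs are fixed. The
nuclear factors $g_{ph}$, $g_{dt}$ (fluence lost in phantom and detector)
and $S_{MC}$ (dose per primary) cannot be derived from electromagnetic
physics and are consumed from the shipped fixture tables; `dose_for_snr()`
refuses to default them to 1. Dose converts to mGy via
$1\,\mathrm{MeV\,mm^{-3}}(\mathrm{g/cm^3})^{-1} = 1.602\times10^{-4}$ mGy.

The MTF combines the Gaussian scattering factor with the pixel aperture
(sinc) and sampling comb; the comb convolution is an aliased-replica sum
truncated at $\pm3$ replicas (the neglected tail is $<10^{-6}$ for the
widths of interest) and recoverable frequencies are capped at Nyquist
$1/(2a)$. Pixel defaults mirror the study setup: 1 mm for SNR/dose, 0.25 mm
for resolution figures. `select_energy()` implements the two published
beam-selection policies; the fixed-MTF policy bisects on energy (MTF is
monotone in energy) to a 0.05 lp/cm tolerance, subject to the hard
70 MeV/u exit-energy floor — which binds for every ion heavier than the
proton, as the fixture table shows.

## The Monte Carlo validator

`simulate_beam()` is a condensed-history electromagnetic Monte Carlo in one
transverse plane: per 1 mm step (the step limiter is configurable) it
applies deterministic RK4 mean energy loss, a Gaussian straggling draw with
per-step variance $k_2\Delta x$, and a correlated bivariate
(direction, position) kick with the step's Fermi–Eyges moments
($T\Delta x$, $T\Delta x^2/2$, $T\Delta x^3/3$). The world is the 20 cm
water cylinder centred in a 30 cm box whose air is treated as vacuum;
trackers sit at the entry face, mid-plane and exit face. Histories are
fully reproducible from a seed.

What it emulates: straggling-dominated exit-energy distributions, the
growth of transverse spread, the conditional (entry/exit-binned) path
spread that validates the envelope, and the lateral structure of
radiograph noise — including the off-centre noise bumps of proton
radiographs, which arise where the chord-length gradient of the cylinder
meets a still-substantial lateral diffusion, and which vanish for carbon.
What it does not contain: nuclear interactions and fragments, detector
energy resolution and material budget, realistic tracker spacing,
out-of-plane scattering, and non-Gaussian straggling/scattering tails
(Vavilov/Landau, single-scattering). Passing the cross-validation therefore
shows internal consistency of the electromagnetic model, not fidelity to
measured radiographs.

Default problem sizes: validation tests run 2–3×10⁴ histories with 5–15%
statistical tolerances; the end-to-end checks use 10⁵ histories (10%
tolerances) and 2×10⁵ for the proton bump profile. A 10⁵-history cylinder
run takes a few seconds on one core.

## Degenerate inputs and error behaviour

Energies below 1 MeV/u, depths at or beyond the range, inverted energy
pairs, negative frequencies and missing nuclear factors all raise explicit
errors. Stopped Monte Carlo histories are flagged and excluded from exit
statistics rather than dropped silently; under-populated radiograph pixels
and exit bins are flagged or dropped with a warning. A zero envelope
degenerates to the single straight path, and the complete-mode MTF returns
Nyquist with a flag when the 10% crossing is sampling-limited.

## Known limitations

The model is specific to a uniform water cylinder: the SNR relation is a
central-voxel statement and the noise model has no heterogeneity, so the
well-known noise amplification around high-gradient interfaces is out of
scope. Nuclear physics enters only through fixture tables. The stopping
model's missing density effect makes high-energy ranges ~1% long. All
scattering is Gaussian, which underestimates tails that a dE–E filter
would partly remove in practice.
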