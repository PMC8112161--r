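# ionct

Image-quality modelling for energy-loss ion computed tomography.

Ion CT reconstructs a map of relative stopping power (RSP) from the energy
lost by individual ions — hydrogen, helium, lithium, boron or carbon —
crossing the patient. Image quality is bounded by electromagnetic physics:
multiple Coulomb scattering blurs each particle's path (limiting spatial
resolution), and energy-loss straggling plus path variability add noise to
the measured water-equivalent thickness, WET (limiting the signal-to-noise
ratio attainable per unit dose). `ionct` implements an analytic model of
this chain for a uniform water cylinder, and a seeded condensed-history
electromagnetic Monte Carlo that validates the analytic moments at desk
scale. It is aimed at medical-physics researchers comparing ion species and
beam energies for particle imaging.

## The model

For an ion of charge *Z*, mass number *A* and energy per nucleon *E*
crossing water:

- **Stopping power** (Bethe–Bloch, no density/shell corrections):
  *S(E) = Z²K/β² [ln(2mₑc²β²/(I(1−β²))) − β²]*, with *K* = 0.170 MeV/cm and
  *I* = 78 eV for water. CSDA range and depth–energy transport follow by
  integration.
- **Scattering** (Fermi–Eyges moments with the Highland constant
  *E₀* = 13.6 MeV/c): position/direction covariance accumulated as
  *∫(x−u)ⁿ du/(pv(u)²X₀)*. Conditioning the Gaussian process on the entry
  vector and the measured exit position gives the tracker-constrained path
  envelope *σ(x)*, zero at both trackers and maximal near mid-depth.
- **Straggling** (Tschalär): *σ²(E_out) = k₁²(E_out)∫k₂/k₁³ dE*, with *k₂*
  the Bohr straggling power (0.0871 MeV²/cm for unit charge) with
  relativistic correction.
- **WET noise**: *σ_WET = σ_E/S(E_out)*; scattering and straggling add in
  quadrature in energy.
- **Image quality**: *SNR = √(3Ma²/π²)·S(E_out)√N_D·RSP/σ_E* in the centre
  of the cylinder; central-voxel dose for a target SNR,
  *D_c = π²SNR²σ²_WET·g_ph·g_dt·S_MC/(3a⁴ρRSP²)*, with the nuclear factors
  *g_ph*, *g_dt*, *S_MC* taken from published full-Monte-Carlo tables
  shipped as fixtures; and the modulation transfer function
  *MTF(ε) = sinc(εa)·exp(−2π²σ²ε²) ⊛ III_{1/a}*, whose 10% crossing
  (MTF₁₀%, lp/cm) is the spatial-resolution metric, capped at the Nyquist
  frequency 1/(2a).

## Worked example

```r
library(ionct)

# Electromagnetic noise for a 200 MeV proton beam crossing 20 cm of water
nb <- noise_budget(200, "proton", thickness_mm = 200)
glance(nb)
#>   ion    E0_MeV_u Eout_MeV_u sigma_wet_mm straggling_fraction
#> 1 proton      200       87.7         2.65               1.000
```

The beam leaves the phantom at 87.7 MeV/u; the WET noise per particle is
2.65 mm, essentially all of it from straggling (the path-ensemble scattering
term is negligible for an on-axis chord).

```r
# Spatial resolution from the constrained scattering envelope
env <- constrained_envelope(200, "proton", thickness_mm = 200)
glance(env)
#>   ion    E0_MeV_u thickness_mm conditioning  sigma_mid_mm sigma_max_mm mtf10_lp_cm
#> 1 proton      200          200 exit_position        0.614        0.675        5.57
```

The path uncertainty at mid-depth is 0.61 mm, i.e. a scattering-only
MTF₁₀% of 5.6 lp/cm — protons are the softest imaging beam.

```r
# Dose penalty of heavier ions at equal SNR (fixed 26 cm range scenario)
dose_ratio_table(ion_table("fixed_range"))[, c("ion", "sigma_wet_mm", "excess_dose_pct")]
#>   ion     sigma_wet_mm excess_dose_pct
#> 1 proton          2.52             0
#> 2 helium          1.26            36.5
#> 3 lithium         1.01            74.1
#> 4 boron           0.75            46.1
#> 5 carbon          0.66            40.9
```

Although heavier ions are quieter per particle, their nuclear attenuation
and larger dose per primary mean helium needs ~37% more dose than protons
for the same SNR, lithium ~74%.

```r
# Beam-energy selection: helium at a 10 lp/cm spatial-resolution target
select_energy("helium", "fixed_mtf", target_lp_cm = 10)
#>   ion    policy    E_MeV_u mtf10_lp_cm condition
#> 1 helium fixed_mtf    190.        10.3 exit_energy_floor
```

For helium the 70 MeV/u exit-energy floor binds before the resolution
target: the minimum crossing energy already resolves better than 10 lp/cm.

A command-line shell over the same functions is installed at
`system.file("cli", "ionct", package = "ionct")` with subcommands
`iontable`, `snrdose`, `mtfscan`, `mcsim` and `validate`.

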