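# vesiscope

Multiscale characterization of lipid vesicles (liposomes) in polymer
solutions, for membrane biophysicists and soft-matter rheologists who need to
go from raw instrument exports to derived physical quantities in one
reproducible pipeline.

A vesicle suspension in a polymer-crowded medium is probed at five scales,
and `vesiscope` implements the analysis for each:

| Measurement | Model | Result |
|---|---|---|
| DLS correlogram | `g2 − 1 = A·exp(−2Γτ)`, `Γ = D_T·q²` | diffusion constant, hydrodynamic diameter (Stokes–Einstein) |
| SAXS profile | Bragg peaks at `q*`, `2q*`; `d = 2π/q*` | lamellar repeat spacing, lamellarity class |
| DSC thermogram | baseline-subtracted exotherm | transition temperature `T_c`, specific enthalpy `ΔH` |
| Viscosity ramp | Einstein `η_r = 1 + 2.5φ`; Krieger–Dougherty `η_r = (1 − φ/φ_max)^(−A·φ_max)` | relative viscosity, thermal-thickening jump/width, model residuals |
| TCSPC decay | biexponential fit; Förster–Hoffman `ln τ = A + B·ln η` | intensity-weighted lifetime, bilayer microviscosity |

Cross-cutting quantities tie the stages together: the adsorbed-polymer layer
thickness `δ = (d_mix − d_neat)/2` and its molecular-weight scaling
`δ ∝ Mw^ν`, the geometric vesicle volume fraction from bilayer geometry
(area per lipid, bilayer thickness, lipid concentration), and mean
interparticle distances `L = d·[(2/(πφ))^{1/3} − 1]`.

Because raw data for such studies are typically available only on request, a
deterministic synthetic-data generator (`gen_study()`) emulates the whole
study design — neat vesicles plus polymer conditions at gel- and fluid-phase
temperatures — so the full pipeline (`run_study()`) is testable end to end
against a ground-truth manifest.

## Worked example

```r
library(vesiscope)

# --- DLS: simulate a vesicle correlogram and size it ---
tr <- gen_correlogram(D = 5.2e-12, q = compute_wave_vector(633e-9, 1.33, 173),
                      amplitude = 0.9, noise_sd = 0.01, n_points = 200, seed = 1)
fit_correlogram(tr)
#> DLS single-exponential fit 'synthetic D=5.2e-12'
#>   A        = 0.9011
#>   Gamma    = 3614.09 1/s
#>   D_T      = 5.20361e-12 m^2/s
#>   diameter = 120.7 nm

# --- FLS: calibrate a molecular rotor and invert a lifetime ---
cal <- fit_forster_hoffman(c(24.01, 20.61), c(28.75, 1.02), temperature_C = 35)
cal
#> Forster-Hoffman calibration at 35 C: ln(tau/ns) = 3.0249 + 0.04573 ln(eta/cP) (2 pairs)
microviscosity_from_lifetime(23.91, cal)
#> [1] 26.24 (cP)

# --- Rheology: volume fraction from geometry, hard-sphere predictions ---
phi <- vesicle_volume_fraction(vesicle_geometry(119.9))$phi
c(phi = phi, einstein = einstein_model(phi), kd = krieger_dougherty(phi))
#> phi = 0.097; Einstein eta_r = 1.244; KD eta_r = 1.327
```

The fitted rate (3614 s⁻¹) reproduces the generating `Γ = D·q²` within the
1% trace noise, and dividing by `q²` recovers the diffusion constant, which
Stokes–Einstein converts to a ~120 nm hydrodynamic diameter at 35 °C. The
two-point Förster–Hoffman calibration inverts a 23.91 ns mean lifetime to a
26.24 cP bilayer microviscosity — a vesicle whose membrane interior is some
thirty-fold more viscous than the bulk water around it. The geometric volume
fraction (~9.7% including enclosed water) puts the suspension where the
Krieger–Dougherty prediction (1.33) separates visibly from the dilute
Einstein line (1.24).

For the full study design — all five stages per condition, layer-thickness
scaling, model comparison and report tables — see `?gen_study`, `?run_study`
and the methods vignette in `vignettes/`.

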