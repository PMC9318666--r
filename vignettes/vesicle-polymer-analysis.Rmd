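---
title: "Methods: multiscale analysis of vesicle-polymer solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale analysis of vesicle-polymer solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiscope)
```

## Scope

`vesiscope` analyses the five kinds of measurement that together characterize
a suspension of lipid vesicles (liposomes) in a polymer-crowded aqueous
medium, from the nanometre scale of a single bilayer to the bulk rheology of
the suspension:

* **DLS** intensity autocorrelation functions, for translational diffusion
  and hydrodynamic size;
* **SAXS** 1D profiles, for lamellar Bragg spacings and lamellarity;
* **DSC** thermograms, for the gel-fluid transition temperature and its
  specific enthalpy;
* **steady-shear viscosity ramps**, for relative viscosity, hard-sphere model
  comparisons and the thermal-thickening step at the lipid melting
  transition;
* **TCSPC fluorescence decays** of a membrane-bound molecular rotor, for
  bilayer microviscosity via a Förster-Hoffman calibration.

Because raw instrument data for such studies are rarely deposited, the
package ships a deterministic synthetic-data generator whose forward models
are exactly the models the analysis stages assume. Every analysis routine is
validated by round-tripping generator output; the limits of that validation
are discussed at the end.

## Dynamic light scattering

A dilute suspension of monodisperse spheres gives a single-exponential
intensity autocorrelation,
$$ g_2(q,\tau) - 1 = A\,e^{-2\Gamma\tau}, \qquad \Gamma = D_T\,q^2 , $$
with $q = 4\pi n \sin(\theta/2)/\lambda$ the scattering wave vector.
`fit_correlogram()` fits $A$ and $\Gamma$ by Levenberg-Marquardt least
squares. The decay rate of a physical correlogram is positive, and the
package uses the positive-rate convention $\Gamma = D_T q^2$ throughout
(some texts carry a minus sign from the field-correlation phase factor; only
the magnitude is measurable). Initialization is deliberately simple and
deterministic: $A_0$ is the first point and $\Gamma_0$ comes from the delay
at which the amplitude has fallen to $A_0/e$; tolerance is $10^{-10}$ on the
sum of squares with at most 1000 iterations. Traces that do not decay, or
fit to a non-positive rate, are flagged `converged = FALSE` rather than
producing numbers.

The hydrodynamic radius follows from Stokes-Einstein,
$R_h = k_B T / (6\pi\eta D_T)$, using the solvent viscosity at the trace
temperature. For pure water the package uses a Vogel correlation
$\eta/\mathrm{mPa\,s} = \exp(a + b/(T - c))$ with $a = -3.327$,
$b = 451.43$ K, $c = 157.55$ K, fitted once to the standard reference values
at 10-40 °C in 5 °C steps; the correlation reproduces those references to
better than 0.1%, comfortably inside the 1% the sizing chain needs. A linear
interpolation of the reference table would be an acceptable alternative; the
closed form was chosen so that the correlation extrapolates smoothly inside
0-100 °C and differentiates cleanly.

Temperatures are degrees Celsius at every user-facing boundary and Kelvin
internally.

### Adsorbed-layer thickness and its scaling

When polymer chains physisorb onto the vesicles the hydrodynamic diameter
grows; half the increase is the bound-layer thickness
$\delta = (d_\mathrm{mix} - d_\mathrm{neat})/2$. By default $\delta$ is
computed against a configured reference diameter for the neat vesicles
rather than a same-session measurement, because the reference is usually the
better-characterized number; both conventions are one argument away.
Negative $\delta$ (apparent shrinkage, e.g. osmotic dehydration) is
reported, flagged, and excluded from scaling fits, since only positive
thicknesses carry coil-size information.

For a flexible polymer, $\delta$ should scale as the coil size,
$\delta \propto M_w^\nu$ with $\nu \approx 0.5$ for theta and
$\nu \approx 0.59$ for good-solvent statistics. `fit_layer_scaling()` is an
ordinary least-squares line in $(\log_{10} M_w, \log_{10}\delta)$; the slope
is base-invariant because both axes transform together. On the bundled
reference diameters for the DMPC/DMPG-PEG system (neat 119.9 nm; 121.4,
129.6, 135.7, 157.7 nm at 1.5, 20, 100, 400 kg/mol) the four-point fit gives
a slope of 0.562. The nominal good-solvent exponent 0.58 is often quoted for
such data; with only four points and sub-nanometre uncertainties on the
smallest $\delta$, the two are not distinguishable, and the package reports
the least-squares value while the tests accept the 0.58 neighbourhood.

## SAXS lamellar analysis

Stacked bilayers produce equally spaced Bragg peaks at $q^*$ and $2q^*$;
the repeat distance (bilayer plus interlamellar water) is $d = 2\pi/q^*$.
`detect_lamellar_peaks()` works on the profile divided by an iteratively
fitted power-law background (two refit passes excluding points more than two
standard deviations above the line, so the peaks themselves do not lift the
background). Each point in the search window is then studentized against a
local annulus 9-30 grid steps away on either side — a local median and MAD —
which adapts the threshold to the strongly $q$-dependent relative noise of
counting-statistics data and makes the decision invariant to an overall
intensity rescale. A peak is accepted where at least three consecutive
points exceed `prominence` (default 3) local MADs: a real Bragg peak is
always broader than the grid because of instrumental resolution, whereas
isolated noise excursions almost never persist for three points. Ties
resolve to the lower-$q$ point. The MAD carries a tiny floor relative to the
local ratio level so that noiseless profiles stay peak-free.

Classification follows the peak pattern: both orders present with
$q_2/q_1 \in [1.9, 2.1]$ is `multilamellar`; no peaks is `unilamellar`; an
unpaired peak is `indeterminate`. Temperature on a profile is metadata only —
repeat distances do shift a few percent between gel and fluid phases
(6.28 nm vs 6.82 nm in the bundled reference values), so $d$ is always
reported against the profile it came from.

`low_q_power_law()` reports the log-log slope over a chosen window; steeper
low-$q$ scattering is the signature of dissolved polymer.

## DSC

`detect_transition()` subtracts a linear baseline fitted to the outer 15% of
the temperature range, takes the extremum of the baseline-subtracted heat
flow (exotherms are stored positive; readers flip vendor "exo-down"
exports), and measures the full width at half maximum by interpolating the
half-height crossings. Peaks below five baseline noise standard deviations
are reported as no transition.

`integrate_enthalpy()` computes
$\Delta H = \left|\int (\Phi - \Phi_\mathrm{base})\, dT\right| / \beta$ with
$\beta$ the scan rate in °C/s, giving J per gram of sample. Two numerical
choices matter at realistic noise levels. First, the linear baseline is
anchored on the *averages* of the outer 5% of the window on each side, not
on two single samples — a single noisy endpoint tilts the baseline and costs
over a percent of area. Second, the integrand is signed and the magnitude
taken at the end; integrating $|\Phi - \Phi_\mathrm{base}|$ pointwise would
rectify baseline noise into a systematic positive bias. Both choices leave
the result exactly invariant to adding any linear function of temperature.
The default window is $T_c \pm 4\,\mathrm{FWHM}$, clipped to the data; a
warning flag is raised when the local baseline slopes at the two window
edges disagree strongly, the usual sign that the window clips the peak.

Specific enthalpies are reported per gram of sample throughout;
normalization to lipid mass is a composition question left to the caller
(typical lipid melting enthalpies are ~20 J per gram of lipid, so per-sample
values at ~2 wt% lipid are naturally in the 0.2-0.4 J/g range).

## Rheology

`relative_viscosity()` divides a sample ramp by a reference ramp after
linear interpolation onto common temperatures. Two parameter-free
hard-sphere predictions are provided: Einstein's dilute limit
$\eta_r = 1 + 2.5\phi$ and Krieger-Dougherty
$\eta_r = (1 - \phi/\phi_\mathrm{max})^{-A\phi_\mathrm{max}}$ with the
submicron-sphere literature constants $A = 2.7$, $\phi_\mathrm{max} = 0.71$.
`compare_models()` deliberately performs **no fitting**: the volume fraction
comes from vesicle geometry, so residuals against the models are a physical
statement, not a regression.

The geometric volume fraction counts the whole outer sphere — a vesicle
carries its enclosed water with it hydrodynamically. For a unilamellar shell
of outer radius $R$, bare bilayer thickness $t$, area per lipid $a_L$, lipid
molar mass $M$ and mass concentration $c$:
$$ N_\mathrm{lipid} = \frac{4\pi\left(R^2 + (R-t)^2\right)}{a_L}, \qquad
   \phi = \frac{c\,N_A}{N_\mathrm{lipid} M}\cdot\frac{4}{3}\pi R^3 . $$
Defaults are standard fluid-phase DMPC values — $t = 4.4$ nm,
$a_L = 0.60$ nm² (gel-phase analogues ~4.8 nm and 0.47 nm²), $M = 678$
g/mol — and every one is config-visible, because the SAXS repeat distance
(6.28-6.82 nm) *includes* interlamellar water and must not be mistaken for
the bare thickness. With the reference composition (119.9 nm vesicles at
17 g/L) the chain gives $\phi \approx 0.097$, consistent with the ~9.2%
used in the reference analyses given the uncertainty in $a_L$ and $t$.

Interparticle geometry uses the random-sphere estimate
$L = d\,[(2/(\pi\phi))^{1/3} - 1]$ for the mean face-to-face distance and
`bound_chain_gap()` subtracts twice the adsorbed-layer extent (typically
$2R_g$) from it; a negative gap flags overlapping bound layers.

`thickening_metrics()` quantifies the viscosity step at the gel-fluid
transition. Plateaus are medians over windows at $T_m \pm [2, 6]$ °C by
default — the near offset avoids the ripple-phase region around the
transition. The jump is plateau-to-plateau in percent (a peak-to-baseline
variant is also reported, since transient maxima at the transition are
common), and the width is the span between the 10% and 90% crossings of the
normalized step. The step is monotone between plateaus, so the rise profile
is estimated by isotonic regression, which is the natural noise-robust
estimator here and needs no bandwidth choice. For transitions wider than
~4 °C the default plateau windows overlap the rise and bias the jump low;
the offsets are an explicit argument, and the package's own wide-step
analyses use $\pm[5, 15]$ °C, chosen from the logistic geometry (the
$[2,6]$ window median sits at 92% of a 7 °C-wide step, the $[5,15]$ window
at 99%).

## Fluorescence lifetimes and microviscosity

TCSPC histograms are fitted from the peak bin onward (tail fitting) with
$$ c(t) = s\left[f_1 e^{-t/\tau_1} + (1 - f_1) e^{-t/\tau_2}\right] + b , $$
by weighted least squares with Poisson weights $1/\max(c_i, 1)$. The SSR
surface of a biexponential has well-known spurious minima — one rate can
slide to zero and impersonate the background — so the optimizer
(Levenberg-Marquardt with box constraints) is started from a small
deterministic grid of amplitude fractions, rate ratios and background
levels, and the lowest weighted SSR wins. Components are ordered
$\tau_1 \le \tau_2$ and reported as fractions plus a scale. When the two
lifetimes collapse within 5% (or one fraction vanishes) the model is refit
as a single exponential and flagged; forcing two components onto
one-component data only inflates the covariance. Convolution with a stored
instrument response is available but off by default: for lifetimes of tens
of nanoseconds measured with a sub-nanosecond response, tail fitting past
the peak makes deconvolution unnecessary.

The mean lifetime uses intensity weighting,
$\langle\tau\rangle = \sum a_i \tau_i^2 / \sum a_i \tau_i$, which is the
average a steady-state intensity measurement would see and always lies
between the component lifetimes.

A molecular rotor's lifetime tracks the viscosity of its immediate
environment through the Förster-Hoffman relation, linear in log-log form:
$$ \ln\tau = A + B \ln\eta . $$
`fit_forster_hoffman()` fits $A$ and $B$ by least squares over calibration
pairs of known viscosity (a methanol-glycerol dilution series is the usual
choice for hydrophobic probes); with exactly two pairs the fit is the exact
two-point solution. Natural logarithms are used throughout, and the
inversion $\eta = \exp[(\ln\tau - A)/B]$ is exact algebra, so a lifetime
equal to a calibration anchor returns that anchor's viscosity identically.
On the bundled fluid-phase (35 °C) reference anchors, the two-point
solution gives $B = 0.0457$, and the remaining reference lifetimes invert to
their published microviscosities within 1%, a consistency check kept as a
regression test. The printed constants that sometimes accompany such
calibrations can be scale- or labelling-ambiguous; this package therefore
*always* computes $A$ and $B$ from pairs and treats any externally printed
constants as metadata.

One caveat is inherent to the method: the inversion amplifies relative
lifetime error by $1/B$. With $B \approx 0.046$ (fluid phase) a 0.3%
lifetime error is ~7% in microviscosity, and with $B \approx 0.015$ (gel
phase) it is ~20%. This is physics, not implementation; reported gel-phase
microviscosities should always be read with that lever arm in mind, and the
pipeline's round-trip tests compare microviscosities on the log scale with
exactly this error budget.

## The synthetic-data generator

Each generator is the forward model of its analysis stage plus the noise
the instrument class produces:

* `gen_correlogram()`: exponential decay on a log-spaced delay grid spanning
  $0.01/\Gamma$ to $10/\Gamma$, multiplicative Gaussian noise (default 1%);
* `gen_saxs_profile()`: power-law background with optional Gaussian Bragg
  peaks at $2\pi/d$ and $4\pi/d$ (second order at 0.4 times the first, a
  typical weak ratio; configurable), noise $\propto\sqrt{I}$;
* `gen_dsc_trace()`: Gaussian exotherm of prescribed area
  $\Delta H \cdot \beta$ on a linear baseline, additive noise (default
  $2\times10^{-5}$ W/g);
* `gen_viscosity_curve()`: solvent curve times a logistic step; the `width`
  parameter *is* the 10-90% rise span (logistic scale $w/2\ln 9$), so the
  generator and `thickening_metrics()` share one width definition and
  round-trip exactly; multiplicative noise (default 0.5%);
* `gen_decay_histogram()`: per-bin Poisson counts around a multi-exponential
  expectation, optionally IRF-convolved.

Noise defaults are stated assumptions (raw-trace noise levels are almost
never published) and are recorded in the study manifest. Every generator
seeds a local RNG stream and restores global RNG state on exit; a fixed seed
gives byte-identical output.

`gen_study()` assembles the full reference design — one neat condition plus
four polymer molar masses (1.5, 20, 100, 400 kg/mol), probed at 15 °C (gel)
and 35 °C (fluid) — with per-condition hydrodynamic diameters
$d_\mathrm{neat} + 2\delta(M_w)$ from the configured layer scaling
($\delta = 0.0106\,\mathrm{nm} \times M_w^{0.58}$, anchored to the largest
reference layer), diffusion constants from Stokes-Einstein, lifetimes placed
on the configured Förster-Hoffman truth lines, and a manifest of every
generating parameter. `run_study()` is the inverse: it runs every stage and
assembles per-condition tables plus cross-condition derived quantities, with
no randomness anywhere in the analysis, so identical inputs give identical
reports. Missing stage inputs are marked absent, never zero-filled.

**What the generator does not emulate** — and what passing round-trip tests
therefore cannot certify on real data: polydisperse or multimodal size
distributions (a cumulant or CONTIN analysis is out of scope), vesicle form
factors and ripple-phase pretransitions, instrument afterpulsing and dead
time, vendor smoothing of reduced SAXS data, and drifts or non-linear
baselines. The tests certify the estimators against their own model classes
at realistic noise; systematic deviations from those model classes on real
instruments must be judged per dataset.

## Problem sizes and test design

The validation suite runs at the sizes the analyses are designed for:
200-point correlograms, 300-point SAXS profiles, 701-point thermograms,
351-point viscosity ramps and 1200-bin decay histograms at $10^6$ counts.
Ensemble properties use 100 seeds (DLS rate recovery, SAXS spacing
recovery) or 50 seeds (lifetime recovery); the full suite completes in well
under a minute. Recovery criteria mirror each stage's noise budget: 2% on
diffusion rates at 1% trace noise, 1% on enthalpy and mean lifetime, one
grid step on Bragg spacings, and the $1/B$-scaled log-viscosity budget
described above.

## Known limitations

* Single-exponential DLS only; polydispersity is accepted as pass-through
  metadata, not estimated.
* The lamellarity classifier needs both Bragg orders inside the measured
  window; a first-order peak at the window edge reads `indeterminate`.
* Two-point Förster-Hoffman calibrations are exact but fragile — an error
  in either anchor propagates undamped; prefer a full dilution series when
  available.
* The geometric volume fraction assumes strictly unilamellar, spherical,
  monodisperse vesicles; each assumption biases $\phi$ upward or downward
  in ways the model comparison cannot separate.
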