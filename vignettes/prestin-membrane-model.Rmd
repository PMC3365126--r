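---
title: "Electro-viscoelastic modeling of prestin-containing membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-viscoelastic modeling of prestin-containing membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prestinmem)
```

## The model

The cochlear outer hair cell (OHC) changes length and, when constrained,
generates force in response to changes in its membrane potential; cells
transfected with the motor protein prestin acquire the same behavior. The
striking experimental fact this package is organized around is that the
*isometric* active force of the OHC keeps an almost constant amplitude and
phase from low frequencies up to roughly 80 kHz, even though both prestin
charge transfer and the surrounding membrane are dissipative.

`prestinmem` implements a linear constitutive model for such membranes in
which the observable strain is the sum of a *passive* (viscoelastic matrix)
part and an *active* (prestin, charge-coupled) part:

* **Mechanics.** Each direct membrane modulus is a spring in parallel with a
  springpot (power-law element). The relaxation kernel is
  $E(t) = C + \eta\, t^{-\nu} / \Gamma(1-\nu)$, the Laplace transform
  $\bar E(s) = C/s + \eta\, s^{\nu-1}$, and the complex modulus
  $C^*(\omega) = C + \eta\,(i\omega)^\nu$ on the principal branch, so the
  storage and loss parts are the matched power functions
  $\eta\,\omega^\nu\cos(\nu\pi/2)$ and $\eta\,\omega^\nu\sin(\nu\pi/2)$.
  For the orthotropic cylindrical OHC wall the elastic part is the 2x2
  matrix $[C_{11}, C_{12}; C_{12}, C_{22}]$ (axial = 1, circumferential =
  2); for the spherical transfected cell a single area modulus $K$. Creep
  kernels are defined through the Laplace-domain reciprocity
  $\bar J(s) = \bar E(s)^{-1}/s^2$ and inverted numerically.
* **Electricity.** Prestin charge transfer behaves as a capacitor $C_{sp}$
  and resistor in series with RC time $\tau_e$: a first-order filter with
  gain $1/\sqrt{1 + (\omega\tau_e)^2}$ and phase $-\arctan(\omega\tau_e)$.
  The step response of the charge per unit area is
  $C_{sp} V (1 - e^{-t/\tau_e})$.
* **Coupling.** Active strain is proportional to the transferred charge with
  coefficients $\alpha_i$ that enter only through the products
  $a_i = \alpha_i C_{sp}$ (strain per volt). By thermodynamic symmetry the
  same kernels couple the resultant history to generated charge.

### The isometric force and its frequency invariance

Under isometric conditions the total strain vanishes, passive strain cancels
active strain, and the axial resultant under harmonic stimulation is
proportional to
$$
F(\omega) \propto \frac{\tilde C^*(\omega)}
  {\sqrt{1 + (\omega\tau_e)^2}}\,e^{i\varphi_e(\omega)},
\qquad
\tilde C^*(\omega) = \bigl(C_{11} + \eta(i\omega)^\nu\bigr) a_1 +
  C_{12}\, a_2 .
$$
Both the viscoelastic numerator and the prestin-filter denominator increase
with frequency; their ratio — the normalized amplitude returned by
`isometric_force()` — varies far less than either factor, and the total
phase is a positive viscoelastic part plus the negative prestin part. With
$\nu = 1$ (Kelvin-Voigt mode) the numerator grows like $\omega$ and no such
balance occurs: the predicted force rises steeply, contradicting the
broadband observations. That contrast is the package's central qualitative
result and is asserted in the acceptance suite.

```{r force}
p <- default_ohc_params()
om <- 2 * pi * 10^seq(3, log10(8e4), length.out = 7)
round(isometric_force(p, om)$amplitude_norm, 3)
round(isometric_force(p, om, model = "kelvin_voigt")$amplitude_norm, 1)
```

### Mechanically evoked charge under voltage clamp

With the potential clamped, pressure or strain histories generate charge
through the same kernels. For a thin pressurized shell $N_1 = \Delta P
r_c/2$, $N_2 = \Delta P r_c$ (cylinder) and $N = \Delta P r_c/2$ (sphere),
giving closed forms: step pressure builds charge as $1 - e^{-t/\tau_e}$;
ramp pressure gives an exponential transient plus a time-linear regime. A
constant axial strain rate on the volume-preserving cylinder
($\dot\varepsilon_2 = -\dot\varepsilon_1/2$) drives resultant rates
$\dot N_i(t) = E_{ij}(t)\dot\varepsilon_j$ whose springpot part introduces
the transient integral
$$
T(t) = \int_0^t \bigl(1 - e^{-(t-u)/\tau_e}\bigr)\,u^{-\nu}\,du
     = \frac{t^{1-\nu}}{1-\nu} - \tau_e^{1-\nu}\,G(t/\tau_e),
\qquad G(x) = e^{-x}\!\int_0^x e^{s} s^{-\nu}\,ds .
$$
$G$ is a lower incomplete gamma function of negative argument; it is closely
related to the generalized exponential integral
$E_\nu(x)=\int_1^\infty e^{-xu}u^{-\nu}du$ (exported as
`generalized_expint()`), which solves the same first-order recurrence
family at positive argument. We evaluate $G$ by an all-positive power
series for $x \le 30$ and an asymptotic series beyond, both checked to
1e-9 against 50-digit references, and cross-check the whole charge curve
against a brute-force convolution oracle (`charge_convolve()`).

Signs follow the resultant-strain state: positive internal pressure gives
positive resultants and negative charge; axial *compression* gives negative
resultants and positive charge. The library returns signed charge; the CLI
offers `--magnitude`.

## Parameters: values, units, provenance

All internal quantities are SI (N/m, s, F/m², C/m², rad/s); configs may
declare `tau_e` in µs. Defaults (`default_ohc_params()`,
`default_sphere_params()`) carry citation strings retrievable with
`param_citations()`. Two classes of defaults must be distinguished:

* **Anchored values.** $\nu = 0.7$ (optimal power-law exponent for
  broadband OHC force data, at the upper end of published cell-rheology
  exponents), $\tau_e = 5\ \mu s$ (filter approximation of the
  Fokker-Planck charge-transfer model), $K = 0.24$ N/m (bilayer area
  modulus), and the sphere coupling $a = -0.05\ \mathrm{V^{-1}}$, which is
  reproducible from first principles via
  `alpha_csp_from_displacement(-0.1e-6, 5e-6, 0.4)` (a 0.4 V potential
  change displacing a 5 µm HEK cell by 0.1 µm).
* **Representative values.** The individual orthotropic moduli and OHC
  couplings are not uniquely pinned by public tabulated data. We ship
  $C_{11} = 0.06$, $C_{12} = 0.04$, $C_{22} = 0.08$ N/m — the area-modulus
  scale of published OHC wall estimates (~0.07 N/m), circumferentially
  stiffer as expected from the circumferential actin filaments — and
  $a_1 = -0.08$, $a_2 = +0.03\ \mathrm{V^{-1}}$, whose magnitudes come from
  electromotile length/radius changes per volt and whose opposite signs and
  ~0.4 ratio reproduce every qualitative sign constraint at once: negative
  charge for applied pressure, positive charge for axial compression
  (which structurally requires $|a_2 N_2| > |a_1 N_1|$ under the
  compression resultant state), and a spherical-cell charge exceeding the
  cylindrical one at equal radius.
* **Derived default.** $\eta = 6.5\times10^{-6}\ \mathrm{N\,s^{\nu}/m}$ is
  *derived*, not transcribed: with $\nu$ fixed at 0.7 it is the
  least-squares fit of the normalized amplitude model to a flat unit
  target over 1–80 kHz — the same estimation procedure a broadband
  force-invariance data set implies, with the flat target standing in for
  the untabulated microchamber data. The resulting band is about
  [0.77, 1.14] over 1–80 kHz, against a ~27-fold Kelvin-Voigt rise at the
  same viscosity. This value was fixed once, before the test thresholds
  were written, and is not revisited.

## What the synthetic generator does and does not emulate

`synth_force_sweep()` draws log-spaced frequencies (default 10 Hz–100 kHz),
evaluates the exact forward model, and applies mean-one multiplicative
lognormal amplitude noise (CV given by `noise_cv`) and additive Gaussian
phase noise. This emulates the *dispersion* of microchamber force data but
none of its systematic structure: no frequency-dependent measurement bias,
no cantilever/electrode dynamics, no increase of scatter above 80 kHz, and
the "truth" is by construction the model itself. A green recovery test
therefore establishes estimator correctness and identifiability under the
stated noise — not model adequacy for any real cell.
`synth_filter_surface()` likewise uses a bell-shaped synthetic stand-in for
the charge-transfer voltage profile, which `fit_tau_e()` profiles out, so
only the frequency axis carries physics.

## Estimation

`fit_power_law()` minimizes squared log-amplitude residuals over
$(\eta, \nu)$ by Nelder-Mead in $(\log\eta, \operatorname{logit}\nu)$
coordinates with a 4x4 multi-start grid; it recovers noiseless parameters
to 1e-6 and, at the reference design (n = 30, 5% noise, 1–80 kHz), has
single-fit standard deviation of about 0.03 in $\hat\nu$ with bias below
0.02 (asserted over 100 seeds). Non-convergence and bound-hitting are
reported in the `fit_result`, never thrown. `fit_tau_e()` is a profiled 1-D
optimization; samples confined to the filter's low-frequency plateau are
flagged unidentifiable rather than returning an arbitrary corner.

## Numerical choices

* **Laplace inversion**: fixed-Talbot contour (M = 32) as primary,
  Gaver-Stehfest (N = 16) as an independent cross-check; they agree to
  better than 1e-6 relative on the creep kernels over t in [1e-7, 1e-2] s.
  The transform is evaluated on the principal branch; only the negative
  real axis (branch cut) is excluded.
* **t = 0 singularity**: kernels are defined for t > 0 only; hereditary
  integrals handle the integrable $t^{-\nu}$ endpoint analytically (series)
  or by a power substitution (quadrature), never by evaluating at 0.
* **Branch and sign conventions**: $(i\omega)^\nu$ on the principal branch
  (phase $\nu\pi/2$), so the loss tangent is positive; phase lag is
  negative; normalization of the force amplitude uses the analytic
  $\omega \to 0$ limit, not the smallest grid point.
* **ODE route**: the filter ODE is integrated with classical RK4 sub-stepped
  to at most $\tau_e/50$; the harmonic closed form is matched to 1e-6 when
  started on the attractor (from rest, the homogeneous transient decays as
  $e^{-t/\tau_e}$ and dominates until ~15 $\tau_e$).
* **Degenerate inputs**: a vanishing elastic numerator
  $C_{11}a_1 + C_{12}a_2 = 0$ makes the normalized force undefined and is
  an error; non-positive-definite moduli, $\nu \notin (0,1)$, and
  non-increasing grids are rejected at validation. $\nu = 1$ exists only in
  the Kelvin-Voigt frequency-domain mode (the time-domain kernel would be a
  delta function).

## Design choices where the design was open

* The springpot is attached to the *direct* moduli only; the cross modulus
  $C_{12}$ stays elastic. This is the unique placement under which the
  isotropic spherical membrane is an exact specialization of the cylinder
  ($C_{11}=C_{22}=K$, $C_{12}=0$), which we require so one code path can be
  validated against the other. Consequence: the 12-entry of the complex
  modulus is frequency-independent.
* The ramp-strain transient is evaluated through $G(x)$ rather than a
  complex-argument exponential-integral identity; `generalized_expint()`
  is still exported (and recurrence-tested) as the standard special
  function of this family at positive argument.
* The Kelvin-Voigt mode keeps every other parameter fixed and takes its
  viscosity as an argument, so viscosity sweeps are inputs, not defaults.
* Residuals are formed in log-log space throughout, matching how broadband
  sweeps are plotted and fitted.

## Known limitations

Linear, axisymmetric, membrane-only (no bending or curvature
electromechanics), isothermal, and voltage-clamped for all charge
computations; mixed voltage-plus-mechanical loading, osmotic/volume
regulation, hair-bundle mechanics and the microchamber electrode
partitioning are out of scope. The voltage dependence of charge transfer is
exercised only through the harmonic solution of the first-order filter.
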