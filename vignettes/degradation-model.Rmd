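---
title: "Arterial tissue degradation: model, drivers and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial tissue degradation: model, drivers and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculodamage)
```

## The constitutive model

The package models the aneurysmal arterial wall as a fibre-reinforced
hyperelastic solid whose collagen fibres degrade under supra-physiological
loading. All solid-side quantities are in kPa. The strain energy at a
material point with right Cauchy–Green tensor $C = F^{\mathsf T}F$ is

$$\Psi = \underbrace{c_1\!\left(I_1/I_3^{1/3} - 3\right)}_{\text{elastin
matrix}} + \underbrace{\epsilon_1\!\left(I_3^{\epsilon_2} +
I_3^{-\epsilon_2} - 2\right)}_{\text{volumetric penalty}} +
\sum_{i=1}^{2}\underbrace{\alpha_1\big\langle (1-D_i)\,[\kappa I_1 +
(1-1.5\kappa)K_3^i] - 2\big\rangle^{\alpha_2}}_{\text{collagen fibre
families}},$$

with $I_1 = \operatorname{tr} C$, $I_3 = \det C$, the polyconvex fibre
invariant $K_3^i = \operatorname{tr}[\operatorname{cof}C\,(1 - M_i)]$
built from the structural tensors $M_i = A_i \otimes A_i$, and
$\langle\cdot\rangle$ the Macaulay bracket. The fibre term is tension-only:
it switches on where its argument is positive, and the exponent
$\alpha_2 > 1$ keeps the stress continuous across the switch (the
derivative is an explicit branch, so no $0^{\text{negative}}$ is ever
evaluated). Stresses are $S = 2\,\partial\Psi/\partial C$ (analytic,
assembled from $\partial I_1/\partial C = \mathbf 1$, $\partial
I_3/\partial C = \operatorname{cof}C$ and the closed-form derivative of
$K_3$) and $\sigma = (\det F)^{-1} F S F^{\mathsf T}$. The analytic stress
is verified against central finite differences of the energy in the test
suite rather than trusted; the 6×6 material tangent is provided as a
finite-difference operator with damage frozen, which is sufficient for the
quasi-static Newton drivers here.

The packaged human-carotid profile is `material_profile("carotid_table1")`:
$c_1 = 9.02$ kPa, $\epsilon_1 = 499.8$ kPa, $\epsilon_2 = 2.4$,
$\alpha_1 = 1400$ kPa, $\alpha_2 = 2.2$, $\kappa = 10^{-8}$,
$\beta_f = 39.87^\circ$ ($40^\circ$ is conventional for sphere fibre
fields; the drivers accept either). The dispersion parameter $\kappa$ must
lie in $[0, 1/3]$; the limit damage $D_\infty = 0.96$, intensity scale
$\gamma_\infty = 17.98$ kPa and rate scale $\beta_s = 0.06$ kPa complete
the profile. $\beta_s$ carries kPa units (it is a value of an energy-like
internal variable) and $D_\infty$ is dimensionless, whatever table
typesetting may suggest.

## Damage evolution

Each fibre family carries an independent history state with two internal
variables. The accumulation variable
$\tilde\beta_i = \int_0^t \langle \dot\Psi^{\mathrm{ti},0}_i\rangle\,ds$
integrates the positive rate of the *effective* (fictitiously undamaged)
fibre energy; the Macaulay bracket freezes it during unloading. The
load-level variable $\gamma_i$ records the running maximum of
$\langle \Psi^{\mathrm{ti},0}_i - \Psi^{\mathrm{ti},0}_{\mathrm{ini},i}
\rangle$. Two nested exponential laws convert them to damage:

$$D_{s,i}(\gamma) = D_\infty\left[1 - e^{\ln(1-r_\infty)\,\gamma/
\gamma_\infty}\right], \qquad
D_i(\beta) = D_{s,i}\left[1 - e^{\ln(1-r_s)\,\beta/\beta_s}\right],$$

with $r_s = r_\infty = 0.99$ interpretation constants: the ceiling reaches
99% of $D_\infty$ at $\gamma = \gamma_\infty$, and the damage 99% of its
ceiling at $\beta = \beta_s$. Hence $\gamma_\infty$ sets the plateau
("degradation intensity") and $\beta_s$ the approach rate; the saturation
criterion $\phi = \langle\Psi^{\mathrm{ti},0} -
\Psi^{\mathrm{ti},0}_{\mathrm{ini}}\rangle - \gamma \le 0$ holds after
every update, which pins the ceiling during fixed-amplitude cycling.

Damage initiation is a state of the loading history, not a material
parameter: `damage_activate()` freezes the current $\tilde\beta$ and
effective energy as thresholds. The drivers expose this as "activate after
cycle $N$" (default $N = 1$) or as an effective-energy threshold, since
the physiological limit depends on the boundary-value problem. The history
integral is discretised as forward accumulation of positive energy
increments; a step-refinement test ($10^3$ vs $10^4$ increments) bounds
the discretisation error at $10^{-4}$ in the final damage, and the cyclic
drivers require at least 200 increments per load segment.

## The uniaxial cube drivers

`run_ramp()` and `run_cyclic()` realise the verification protocols: a
linear ramp of the axial nominal traction 0→100 kPa, and ten cycles
0→20→0 kPa with damage activated after the first cycle. The deformation is
homogeneous and diagonal; the two fibre families lie in the plane of the
loading axis at $\pm\beta_f$, so their shear contributions cancel and the
diagonal ansatz is exact, while the two lateral stretches differ
(orthotropic response) and are both solved for. "Load" is the axial
first Piola–Kirchhoff traction — a ramped face load on a unit cube is
nominal by construction. Each increment is a damped Newton solve on the
three principal stretches (residual tolerance $10^{-10}$ kPa, forward
finite-difference Jacobian with step $10^{-7}$, step-halving line search,
at most 50 iterations); damage is frozen within the Newton loop and
updated once on convergence, which is admissible because increments are
small (refinement-tested).

Two behaviours of the calibrated model deserve explicit statement, because
they shape what the drivers report:

* **Degradation is abrupt at these amplitudes.** At 20 kPa the undamaged
  fibre argument $K_3 - 2$ is only about $8\times10^{-3}$, so a damage of
  a few tenths of a percent already pushes the recruitment threshold
  $2/(1-D)$ past the operating range. Once activated, the fibres disengage
  early in the next loading branch, the material point moves to the
  matrix-carried branch, and the effective energy evaluated there drives
  $\gamma$ far beyond $\gamma_\infty$: damage reaches its ceiling within a
  cycle or two and the response is saturated (cycle-to-cycle damage
  increase below $10^{-6}$) by cycle 3 — comfortably within the expected
  five. After saturation the exponentials underflow, so $D = D_s$ holds to
  double precision; strict inequalities $D < D_s < D_\infty$ are
  meaningful (and tested) only at moderate internal-variable values.

* **Remnant strain lives in the fibre families.** The damage function
  shifts the fibres' stress-free stretch: after damage the fibre argument
  vanishes at a stretch `fiber_recruitment_stretch()` $> 1$, so the fibres
  are slack over a finite stretch range after unloading — that is the
  remnant strain the damage function captures. The tissue-level stretch at
  *exactly* zero applied load returns to one, necessarily: the tension-only
  fibres cannot hold the Neo-Hookean matrix off its unique natural state,
  so the only zero-traction equilibrium is the reference configuration.
  `run_cyclic()` therefore reports both `zero_load_stretch` (identically 1
  to solver tolerance) and `fiber_remnant_stretch` (> 1 after damaging
  cycles); hysteresis between loading and unloading branches appears only
  while damage evolves.

## Fibre fields on a spherical dome

At a surface point $G$ of a sphere centred at $O$ with pole $Z$, the
tangent frame is $\zeta_1 = V_{OZ}\times V_{OG}$,
$\zeta_2 = V_{OG}\times\zeta_1$, with the fixed fallback
$\zeta_1 = (1,1,0)/\sqrt2$ at the poles (triggered when the cross product
norm falls below $10^{-10}$ of the product of the factors' norms). Both
$\zeta$ vectors are normalised before use — otherwise the fibre
directions $A_{1,2} = \cos\beta_f\,\zeta_1 \pm \sin\beta_f\,\zeta_2$
would not be unit vectors and the included angle would not be $2\beta_f$.
The $\pm$ sign convention is the only reading under which the two families
are distinct and enclose $2\beta_f$. `fiber_field()` samples the sphere
with a deterministic Fibonacci lattice, which avoids the poles by
construction while the fallback keeps the map defined there.

## Windkessel outflow and the synthetic inflow

The three-element Windkessel (proximal resistor in series with a parallel
distal resistor and capacitor; the standard RCR reading of the named
elements) is integrated in CGS units: $p = R_p Q + p_c$,
$C\,\dot p_c = Q - p_c/R_d$. The flow is taken piecewise linear between
samples and $p_c$ advanced by the exact exponential solution on each
interval — unconditionally stable, deterministic, and exact in the
resistive limit $C\to 0$, where the pressure must track
$Q(t)(R_p + R_d)$ pointwise. Ten cycles are integrated and the final
cycle retained; periodic steady state is flagged when consecutive cycle
means drift by less than 0.1%. The cycle-mean pressure obeys the mean-flow
identity $\bar p = \bar Q\,R_{\mathrm{tot}}$ because the capacitor term
averages to zero over a period; with the carotid branch values
($\bar Q_b = 2.3$ ml/s, $R_{\mathrm{tot}} = 5.7\times10^4$ g cm$^{-4}$
s$^{-1}$, $k_d = 0.9$, $C = 10^{-6}$ cm$^4$ s$^2$ g$^{-1}$) this gives
98.3 mmHg against the 100 mmHg physiological target.

The synthetic inflow generator emulates a carotid flow pulse by its
summary statistics only: a wrapped-Gaussian systolic peak near $0.28\,T$
with a dicrotic shoulder, perturbed by seeded low-order harmonics, then
mapped through a monotone power remap that pins the minimum and maximum
exactly and matches the mean via a one-parameter root solve. Different
seeds give different admissible shapes with identical statistics
(mean 4.6 ml/s, range 3.0–6.9 ml/s, period 0.8 s at the inlet; halved per
branch). It does **not** reproduce any particular measured waveform shape,
so tests built on it demonstrate robustness of the pressure statistics to
the pulse shape, not fidelity to a patient waveform.

## Wall metrics

TAWSS is the trapezoidal time average of $|\tau_w|$ over one period, with
the periodic-closure convention that the last sample equals the first of
the next cycle. The same quadrature serves `time_average()` for near-wall
pressure, von Mises stress ($\sqrt{3/2\,\operatorname{dev}\sigma :
\operatorname{dev}\sigma}$, the standard convention) and strain magnitude,
which this package defines as the Frobenius norm of the Green–Lagrange
strain $\tfrac12(C - \mathbf 1)$. The relative percentage change
$\Delta f = 100\,(f^{\mathrm d} - f^{\mathrm{nd}})/f^{\mathrm{nd}}$ is
undefined at a vanishing baseline; positions with $|f^{\mathrm{nd}}|$
below a configurable floor (default $10^{-8}$ in field units) are masked
as `NA` rather than returned as unbounded ratios.

## Numerical choices and problem sizes

* SPD validation of $C$ uses a symmetric eigenvalue check with tolerance
  $10^{-12}$ on the smallest eigenvalue; failures raise errors, values are
  never clamped. $C^{-1}$ and $\operatorname{cof}C$ use the closed-form
  3×3 adjugate for determinism.
* The test suite runs the cyclic protocol at 200 increments per segment
  (the minimum the drivers accept) and the ramps at 150–400 increments;
  these sizes keep the whole suite in the low minutes on one CPU while the
  refinement tests bound the discretisation error.
* The benchmark (`run_benchmark_suite()`) executes the full ramp and
  cyclic protocols plus a $\gamma_\infty \times \beta_s$ sensitivity grid
  and writes deterministic CSVs and a JSON report; repeat runs are
  byte-identical.

## Limitations

The package covers the material point, not the vessel: there is no 3-D
fluid–structure coupling, no aneurysm geometry, and wall-shear inputs to
the metrics module must come from elsewhere. Growth, remodelling, fatigue,
healing, viscous damage and relaxed or gradient-enhanced damage
formulations are out of scope. Under dead (stress-controlled) loading the
calibrated model degrades essentially completely once activated, as
discussed above; conclusions about gradual in-vivo degradation should rest
on the internal variables and their laws, not on the post-saturation cube
response.
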