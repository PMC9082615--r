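---
title: "Surfactant adsorption and droplet wetting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surfactant adsorption and droplet wetting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfwet)
```

## The problem

Short-chained alcohols (methanol, propanol, pentanol) are the simplest
amphiphiles: soluble in water, yet preferentially enriched at interfaces.
When such a surfactant is dissolved in a sessile water droplet it adsorbs
to *two* interfaces at once — water–vapor and solid–water — lowering both
surface tensions and thereby shifting the Young force balance that sets the
contact angle. `surfwet` implements the full analysis chain from raw,
MD-style observables (1-D density profiles, radial distribution functions,
adsorption–concentration tables) to the predicted contact-angle change,
together with seeded synthetic generators that produce all of these inputs
with analytically known ground truth.

## Models

### Surface excess and the dividing surface

Adsorption is quantified as the Gibbs surface excess

$$\Gamma = \int_{z_a}^{z_0} c(z)\,dz + \int_{z_0}^{z_b}
  \big[c(z) - c_0\big]\,dz,$$

where $c_0$ is the bulk surfactant number density and $z_0$ the Gibbs
dividing surface of the *water* phase — the plane at which the excess water
adsorption vanishes. `find_bulk()` locates the bulk plateau (maximal
contiguous window whose points deviate less than a relative tolerance,
default 2%, from the window mean; a window narrower than 1 nm is an
error, not an answer). `gibbs_dividing_surface()` exploits that the
equal-area condition is *linear* in $z_0$ on the cumulative trapezoid, so
the root is computed in closed form rather than by bisection — the same
root to machine precision, without an iteration tolerance.
`excess_adsorption()` integrates by the trapezoidal rule at a subinterval
of 0.1 nm (resampling finer grids by linear interpolation); the bulk step
is subtracted analytically as $c_0\,(z_b - z_0)$, so no Heaviside
discretization error enters. Endpoints must sit at least 1 nm outside the
interfacial region (default 1.5 nm beyond $z_0$; the integral is
insensitive to pushing them further into either bulk). For solid surfaces
the effective boundary is instead the water-side half-height crossing of
the head-group density peak (`solid_boundary()`).

All profile operations are side-agnostic: the liquid orientation is
inferred from where the density is high, because slab and surface
geometries naturally come in both orientations.

### Langmuir isotherms by orthogonal distance regression

$\Gamma(c_0)$ is described by the Langmuir isotherm
$$\Gamma = \Gamma_\infty \frac{k_c c_0}{1 + k_c c_0},
  \qquad K = k_c\,\Gamma_\infty,$$
whose low-concentration (Henry) limit $\Gamma = K c_0$ defines the
adsorption coefficient $K$ (a length, in nm). Both measured coordinates
carry uncertainty — for some series the relative error on the
concentration dominates — so `fit_langmuir()` minimizes the *orthogonal*
distance: each point gets a latent true concentration, and the stacked
standardized x- and y-residuals are minimized by Levenberg–Marquardt over
$(\log k_c, \log\Gamma_\infty, \hat c_1,\dots,\hat c_n)$. The
log-parameterization enforces positivity; the parameter covariance is the
corresponding block of the inverse approximate Hessian, which profiles out
the latent coordinates. When uncertainties are absent we deliberately fall
back to ordinary least squares on $\Gamma$: ODR with fabricated weights
would merely disguise an OLS as something better.

Because the Langmuir form degrades where adsorbates start interacting
laterally, fits focus on low concentrations: after an initial pass, points
with $k_c c_0 > 2$ are dropped and the fit repeated once. The cut value is
a package choice (deep saturation carries almost no information about $K$)
and the window actually used is recorded in the fit object.

### Kirkwood–Buff correction and the tension law

Solution non-ideality enters through the Kirkwood–Buff integrals
$G_{ij} = \int_0^\infty 4\pi r^2\,[g_{ij}(r)-1]\,dr$ of the
molecule–molecule and molecule–water pair correlations, via the dilute
chemical potential

$$\beta\mu = \ln c_0 - \ln\!\big[1 + (G_{mm} - G_{mw})\,c_0\big]
  + \mathrm{const}.$$

`kb_integral()` integrates a gridded $g(r)$ by trapezoid and, by default,
averages the running integral over the final 20% of the range — a
finite-range RDF never formally converges, and plateau averaging is the
standard guard; the spread over the averaging window is returned as a
convergence diagnostic and a non-plateaued integral warns instead of
failing.

Integrating the Gibbs adsorption equation $d\gamma = -\Gamma\,d\mu$ along
the Langmuir isotherm, with the KB non-ideality folded into a constant
correction factor

$$\xi = 1 + \frac{(G_{mm} - G_{mw})\,\Gamma_\infty}{K},$$

yields the Szyszkowski-type closed form and its linear limit implemented
in the `tension` functions:

$$\Delta\gamma = \xi\,k_BT\,\Gamma_\infty
  \ln\!\Big(1 - \frac{\Gamma}{\Gamma_\infty}\Big),
  \qquad
  \Delta\gamma \simeq -\xi\,k_BT\,\Gamma .$$

The next term of the expansion is $-(\xi k_BT/2\Gamma_\infty)\Gamma^2$, so
the linear law is trusted for $\Gamma \ll \xi^{-1}\Gamma_\infty$ and
flagged beyond $0.1\,\xi^{-1}\Gamma_\infty$. For hard-sphere-like solutes
$G_{mm} - G_{mw} < 0$ and scales with the molecular volume while
$\Gamma_\infty$ scales with the inverse molecular area, so the correction's
numerator grows linearly with molecular size; but $K$ grows exponentially
with it, hence $\xi$ matters for small molecules (methanol-like
$\xi \approx 0.65$) and tends to 1 for strong adsorbers.

Two modelling points here were genuinely open and are resolved as package
choices:

* **Where $\xi$ appears.** A strictly ideal-solution derivation of the
  linear law (Henry plus ideal $\mu$) has no $\xi$. We keep $\xi$ in the
  linear tension law — and, below, in the linearized droplet equation — so
  that the linear expressions are the exact first-order limits of the
  nonlinear ones; with $\xi = 1$ they reduce to the familiar ideal forms.
  Mixing conventions instead would make the "linear vs full" consistency
  checks false at first order.
* **The quadrature oracle.** The closed form above is exactly the Gibbs
  integration with a chemical potential of constant logarithmic slope
  $\beta\mu = \xi\ln c$ ($\xi$ being the KB slope at the Langmuir
  crossover, where the tension reduction accumulates). The test-suite
  oracle therefore integrates $-\Gamma\,d\mu$ numerically under that same
  slope: the check isolates the integration algebra at $10^{-4}$ relative,
  rather than conflating it with the (first-order) accuracy of treating
  the KB slope as constant.

### Adsorption on soft surfaces and the wetting coefficient

A continuum picture of a molecule (m) adsorbing from water (w) into a soft
surface (s) gives the adsorption free energy

$$\Delta G_s = A_c^{*}\,(\gamma_{sm} - \gamma_{sw}) - A_c\,\gamma_{mw},$$

with $A_c$ the surface-accessible contact area and $A_c^*$ the bare
cross-section. Substituting Young's relation
$\gamma_{sw} = \gamma_{sv} - \gamma\cos\theta$,

$$\Delta G_s = \Delta G_s^{(0)} + A_c^{*}\gamma\cos\theta,
  \qquad
  K_s(\cos\theta) = K_s^{(0)}\,e^{-\beta\gamma A_c^{*}\cos\theta}:$$

adsorption weakens exponentially with surface hydrophilicity. The
geometry enters only through the scale-free ratio $A_c^*/A_m$ — exactly
$1/4$ for a sphere, $1/\pi$ for an infinite cylinder, and between the two
for rod-like molecules; the spherical value is the default
(`cross_section_ratio()`). With
$\Delta G^{(0)} = -\tilde\gamma\,A_m$ one obtains the area-scaling laws
$K_i^{(0)} = b_i\,e^{\beta\tilde\gamma_i A_m}$ ($i = v, s$), fitted by
linear regression of $\ln K$ on $A_m$ (`fit_area_scaling()`), and — by
eliminating $A_m$ — the correlation

$$K_s = b_s \left(\frac{K_v}{b_v}\right)^{\textstyle
  \frac{\tilde\gamma_s - \gamma\,\rho\cos\theta}{\tilde\gamma_v}},
  \qquad \rho = A_c^*/A_m,$$

whose log–log slope decreases linearly with $\cos\theta$
(`ks_kv_correlation()`). The correlation is an algebraic identity with the
two laws it is derived from; the test suite verifies the round trip to
$10^{-10}$.

### The surfactant-laden droplet

With the solid–vapor tension unchanged (well-soluble surfactants do not
populate the dry interface; no hook is provided for that case), the Young
equation of the laden droplet reads

$$\big(\gamma_0 + \Delta\gamma_v(c_0)\big)\cos(\theta + \Delta\theta)
  = \gamma_0\cos\theta - \Delta\gamma_s(c_0).$$

Both reductions come from the nonlinear tension law. Since neither side
depends on $\Delta\theta$ except through the cosine, the equation is
inverted directly with `acos` (the bracket $[-1,1]$ is still policed:
an implied cosine above 1 flags `complete_wetting`, below $-1$
`dewetting`, and values are never clamped). For small changes,

$$\Delta\theta \simeq -\,\frac{k_BT\,c_0\,
  \big(\xi_s K_s + \xi_v K_v\cos\theta\big)}{\gamma_0\sin\theta},$$

whose numerator carries the competition between the two interfaces (the
ideal-solution case $\xi = 1$ is the Lucassen–Reynders combination
$K_s + K_v\cos\theta$). On very hydrophilic surfaces $K_s \ll K_v$ and
$\Delta\theta \propto -\cot\theta$, diverging toward complete wetting as
$\theta \to 0$; on very hydrophobic ones the exponentially growing $K_s$
dominates; surfaces near $\theta = 90^\circ$ are the least sensitive.
Angles are degrees at every user-facing boundary and radians internally.

## The synthetic-data generators

The generators define the study conditions for every statistical test:

* `make_slab_profiles()` builds a water slab with tanh edges (width
  0.25 nm, bulk density 33.3 nm$^{-3}$, slab 5 nm in a 10 nm box — typical
  of ambient-temperature water slabs) and a surfactant profile equal to
  the bulk value modulated by the same edge, plus a Gaussian adsorption
  peak whose area *is* the target excess: the tanh edge is odd about its
  midpoint, so the dividing surface and the constructed $\Gamma$ are known
  exactly, not merely to quadrature accuracy. One face is generated by
  default (a mirrored two-sided mode exists) to avoid the two-face
  averaging ambiguity. Optional multiplicative Gaussian noise is drawn
  from a per-call seeded stream that leaves the session RNG untouched.
* `make_rdf()` produces the three closed-form KB families (ideal,
  hard-sphere, exponential-decay) used as oracles; the hard-sphere step is
  stored as its one-cell average so the trapezoid integral stays
  second-order accurate across the discontinuity. For the exponential
  family the analytic truncation remainder beyond `r_max` is attached.
* `make_isotherm_series()` samples the Langmuir curve and perturbs *both*
  coordinates with independent 5%-scale Gaussian noise (the default study
  condition for recovery tests: 8 concentrations spanning the Henry-to-
  saturation crossover, 5%/5% noise), storing the generating parameters.

What they deliberately do not emulate: near-surface density oscillations
of structured solids, interfacial clustering of larger alcohols (the
saturation deviations seen for pentanol), or any atomistic detail. Passing
recovery tests therefore demonstrates correctness of the estimators on
smooth, Langmuir-consistent data — not robustness to layering artifacts or
isotherm misspecification.

## Numerical conventions

* Internal units: nm, nm$^{-3}$, nm$^{-2}$, mN/m, radians;
  $1$ mol/l $= 0.602214076$ nm$^{-3}$ applied only at I/O boundaries;
  $k_BT = 4.1419$ (mN/m) nm$^2$ at the default 300 K.
* Trapezoid everywhere a gridded integral appears; surface-excess
  subinterval 0.1 nm; step-like fixtures use the half-value convention at
  the discontinuity node, which makes their trapezoid integrals exact.
* ODR: Levenberg–Marquardt with `ftol = ptol = 1e-14`, initialization
  $\Gamma_\infty \leftarrow 1.2\max\Gamma$ and $k_c$ from the lowest
  usable point; non-convergence is an error with the solver message.
* Degenerate inputs fail loudly: ramps with no 1 nm bulk plateau,
  non-decaying water tails, multimodal head-group peaks (candidates are
  listed), fewer than three isotherm points, all-zero adsorption series,
  $\Gamma \ge \Gamma_\infty$, tensions driven non-positive
  (`beyond-model`), angles within 1° of the poles in the linearization.

## Problem sizes

The shipped tests run the recovery studies at 100 seeded series for the
biaxial-noise ODR check (8 concentrations each), 200 seeds for the
3-point area-scaling recovery, 100-point parameter grids for the
quadrature-oracle and algebraic-identity checks, and profile grids of
0.02 nm spacing over 10 nm boxes — sizes chosen so the full suite
completes in a few seconds while keeping the Monte-Carlo medians stable
to well inside the asserted bounds.

## Known limitations

* The Langmuir/ODR machinery knows nothing about adsorbate–adsorbate
  attraction; for strongly clustering surfactants the fitted
  $\Gamma_\infty$ is an effective parameter and the tension law degrades
  at intermediate coverage.
* KB integrals are taken at fixed, dilute-limit values; no
  concentration-dependent or finite-size corrections.
* The continuum wetting model assumes full penetration of the molecule
  into the soft surface; weak adsorbers penetrate less, effectively
  $A_c^* < A_m/4$, and no penetration model is provided.
* No contact-line pinning, hysteresis, autophobing, or spreading
  dynamics: predictions are equilibrium contact angles only.
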