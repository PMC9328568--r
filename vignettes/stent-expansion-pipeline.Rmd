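---
title: "Predicting post-stenting lumen area from cross-sectional geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-stenting lumen area from cross-sectional geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentml)
```

## The problem

Stenting a heavily calcified coronary artery often ends in underexpansion:
the deployed stent fails to reach an adequate lumen area (conventionally
80% of the target area at the nominal stent size), which is associated
with restenosis and thrombosis. The geometry of the calcified plaque in
each cross section — how large an angle the calcification subtends at the
lumen centroid, how thick it is, how much compliant fibrotic tissue
remains — largely determines how far that cross section can be stretched.

`stentml` implements a simulation-driven machine-learning pipeline around
this mechanism. A synthetic vessel generator and a reduced mechanical
surrogate stand in for patient imaging and full finite-element
simulation; the constitutive laws, the eight cross-sectional features,
the regression models, and the train/test protocol are implemented in
full and are the objects of study.

The pipeline is: **generate** a labeled 120-slice vessel segment →
**expand** every slice with a composite-ring surrogate to obtain the
post-stenting lumen area (the label) → **extract** the eight pre-stenting
features → **split** into the leading 90 training and trailing 30 test
slices → **fit** a linear model and ε-insensitive SVR with linear,
polynomial and RBF kernels, on all features and on two three-feature
subgroups → **report** per-slice percentage errors, bias, range, and
ANOVA/t-test group comparisons.

## Constitutive laws

All three tissue constituents use a reduced third-order polynomial
strain-energy density in the invariants of the Cauchy–Green tensor,

$$U = C_{10}(I_1-3) + C_{01}(I_2-3) + C_{11}(I_1-3)(I_2-3) +
  C_{20}(I_1-3)^2 + C_{02}(I_2-3)^2 + C_{30}(I_1-3)^3 + C_{03}(I_2-3)^3,$$

with coefficients in MPa (`tissue_presets()`), under incompressible
kinematics ($\lambda_1\lambda_2\lambda_3 = 1$, so
$I_2 = \sum_k \lambda_k^{-2}$). Two modelling points deserve comment:

* **The seven-term basis.** The coefficient table includes first-order
  terms ($C_{10}$, $C_{01}$) alongside the higher orders; the implemented
  basis is exactly the seven listed terms. The printed summation index
  of the usual formula starts at 1 in both exponents, but the table is
  the operative definition.
* **Plasticity on the nominal stress.** The fibrotic plaque is perfectly
  plastic with a nominal (first Piola–Kirchhoff) yield stress of 0.07 MPa
  at 34% engineering strain. The yield measure is nominal, not Cauchy:
  the fibrotic hyperelastic law evaluated at $\lambda = 1.34$ gives a
  nominal stress of 0.0702 MPa — the printed yield pair is exactly the
  hyperelastic curve's nominal value there — whereas the Cauchy stress is
  0.094 MPa, inconsistent with the pair.

Uniaxial stresses come from the standard incompressible reduction
($\lambda_2=\lambda_3=\lambda^{-1/2}$),
$\sigma = 2(\lambda^2-\lambda^{-1})(\partial U/\partial I_1 +
\lambda^{-1}\,\partial U/\partial I_2)$, and are verified in the tests
against central finite differences of the energy along the same path
(relative step $10^{-5}$, agreement within $10^{-6}$ relative).

The elastoplastic response uses a multiplicative elastic–plastic split
$\lambda = \lambda_e\lambda_p$: loading follows the hyperelastic curve,
caps at the yield stress (plastic flow accumulates in $\lambda_p$), and
unloading follows the hyperelastic curve at the elastic stretch
$\lambda/\lambda_p$, giving a permanent set of
$\lambda_{\max}/\lambda_{yield}$. An earlier design that unloaded along a
straight line with the tangent stiffness at $\lambda_{\max}$ was
discarded: because the fibrotic law stiffens strongly, that line nearly
exhausts its elastic range at physiological recoil magnitudes, which made
the recoil equilibrium — and hence every label — pathologically sensitive
to small geometric differences.

```{r}
uniaxial_nominal_stress(1.34, tissue_preset("fibrotic"))
```

## The composite-ring expansion surrogate

The full 3D contact problem is reduced to a per-slice, one-dimensional
circumferential tension balance. This is the smallest model that keeps
the mechanism of interest: fibrotic stretch produces lumen gain,
calcification resists it.

**Loading.** The lumen boundary is driven toward the balloon circumference
$\pi d_{exp}$ ($d_{exp} = 3.3$ mm). The circumferential stretch partitions
between the calcified arc and the fibrotic arc so that the membrane
tension (nominal stress × effective arc thickness) is equal across arcs,
solved by bracketing and bisection on the tension (tolerance $10^{-8}$ mm
on circumference). Two caps bound the partition:

* the calcified arc stretches at most 2% (`calc_stretch_cap`), an
  idealization of the two-to-four orders of magnitude stiffness contrast
  between calcification (hundreds of MPa) and soft plaque (tens to
  hundreds of kPa);
* the fibrotic arc, once past yield, flows plastically at constant
  tension only up to a lock-up stretch of 2.0
  (`fibrotic_stretch_limit`), representing collagen lock-up near the
  tissue's ultimate stretch. Without this bound, perfect plasticity lets
  any nonzero fibrotic window absorb the entire balloon circumference
  (stretches of 8 and more for 330° calcifications), and no slice could
  ever underexpand — contradicting the clinical phenomenon the pipeline
  is about. With it, slices whose calcified arc leaves too little
  compliant circumference stop short of the balloon.

**Recoil.** After balloon deflation the scaffold, with finite recoil
compliance $s_r$ (mm of circumference per N/mm of tension; 0 = rigid
scaffold), carries the residual inward load of the tissue. Two terms make
up that load, weighted by the pre-stenting arc fractions:

* the fibrotic arc unloading elastically from its maximum stretch
  (permanent set retained, as above);
* the elastic hoop recovery of the arterial wall over the calcified arc:
  the deposit itself is rigid, but it was carried outward to the stent
  radius, stretching the elastic artery behind it, which pushes back.

The final circumference solves
$C_{load} - C = s_r\,F(C)$ by bisection and maps to the post-stenting
lumen area assuming a circular post-stenting lumen. The second recoil
term is a deliberate model ingredient: with fibrotic unloading alone,
more calcification would mean *less* recoverable elasticity and hence
*larger* final lumen, inverting the known direction of the
angle–lumen-gain relationship.

**Calibration.** The default $s_r$ is solved (closed form, see
`calibrate_recoil_compliance()`) so that a calcification-free circular
reference section of 1 mm lumen radius and 0.85 mm wall recoils from the
3.3 mm balloon to a 3.0 mm final lumen diameter — the nominal stent size,
lumen area 7.07 mm². This anchors the recoil scale to the one quantity
the protocol states about the calcification-free limit. The 316L steel
constants of the stent (E = 190 GPa, ν = 0.3, σ_y = 207 MPa) are stored
on `stent_params()` as documentation only: the stent enters the mechanics
purely as a kinematic boundary condition plus the calibrated compliance.

```{r}
sec <- cross_section(0, circle_contour(1, 96), circle_contour(1.85, 96),
                     list(sector_annulus_contour(1.01, 1.31, 0, 120)))
expand_section(sec, stent_params())
```

## The eight features

Per slice: artery area (everything inside the outer contour), fibrotic
area, calcification area, lumen area, calcification angle, maximum
calcification thickness, and the lumen-boundary arc lengths inside and
outside the calcified span. Conventions, all measured about the area
centroid of the lumen:

* **Angle** is the measure of the *union* of the angular intervals
  subtended by all deposits (one scalar per slice that generalizes the
  single-deposit case; overlapping deposits are not double-counted).
* **Thickness** is measured radially along centroid rays (the maximum
  summed chord through calcification over a dense ray grid), consistent
  with the centroid-based angle rather than a wall-normal convention.
* **Arc lengths** partition the lumen contour by whether each boundary
  segment's centroid angle falls in the calcified union, so
  `arclength_c + arclength_f` equals the lumen perimeter exactly. This
  convention reproduces the expected strong positive coupling between
  angle and `arclength_c` and negative coupling with `arclength_f`.
* **Fibrotic area** is `area_a - area_l - area_c`; the outer-contour area
  includes the lumen. Note this makes the four area features exactly
  linearly dependent, so the linear model's 8-feature design is
  rank-deficient by construction; the fit drops the aliased coefficient
  with a logged warning (predictions are unaffected).

Neighbor averaging replaces each feature by its mean over the slice and
up to four slices on each side, truncating at segment ends. Only input
features are averaged; labels are not.

## The synthetic vessel generator

The generator emulates a stented segment reconstructed from intravascular
imaging: 120 slices at 0.1 mm spacing (the bookkeeping helper
`axial_positions(26, 7, 0.1)` reproduces the half-open sampling of a
26 mm vessel minus 7 mm margins). Per-slice lumen radius, wall thickness,
total calcification angle and deposit thickness are Gaussian fields along
the axis: white noise smoothed with a Gaussian kernel of width
`axial_correlation_length` and rescaled to the configured mean and sd.
Deposits are annular sectors seated on the lumen boundary — the angle is
controllable by construction — split between up to two deposits on
roughly opposite sides. The lumen is a circle with a mild (4%)
second-harmonic perturbation whose orientation drifts along the axis.

Defaults (one choice, stated here, used throughout): lumen radius
1.0 ± 0.10 mm; wall 0.85 ± 0.06 mm; calcification angle 90 ± 55°
(spans roughly 0–180°, with 180° the usual critical value of OCT calcium
scores, clipped at 340°); deposit thickness 0.30 ± 0.06 mm;
correlation length 0.6 mm. The correlation length deserves a note: it
sets the number of independent lesion-scale patches per segment
(about ten at 0.6 mm). Much longer correlation lengths leave the trailing
30-slice test segment statistically unlike the leading 90 training
slices, and every regression model fails by construction — a regime in
which the segment protocol itself is meaningless. The chosen default
makes the protocol informative while keeping visible axial structure.

What the generator does *not* emulate: imaging speckle and segmentation
error, lipid/necrotic tissue classes, irregular (non-sector) deposit
shapes, bifurcations, and any axial mechanical coupling between slices.
Passing tests on this synthetic data therefore demonstrate the internal
consistency of the pipeline and the mechanistic direction of its
predictions, not clinical accuracy on real vessels.

## Regression stage

* **Linear model**: ordinary least squares with intercept, on the raw
  feature scale.
* **SVR**: ε-insensitive support vector regression in the soft-margin
  form (the hard-margin objective is printed in idealized treatments;
  real data are not exactly ε-representable). Defaults C = 1, ε = 0.1 on
  standardized targets, degree 3, γ = 1/n_features on standardized
  features, all exposed in `model_spec()`. Features and targets are
  standardized before kernel evaluation (constant columns are left
  unscaled; a constant target short-circuits to a constant predictor).
  The libsvm solver is deterministic; its termination tolerance is
  exposed (`solver_tolerance`) and is tightened in the dual-QP
  cross-check tests.
* **Evaluation**: per-slice signed percentage error
  $100(\hat y - y)/y$, bias (mean), range, and maximum absolute area
  difference. Groups of error vectors are compared with one-way
  fixed-effects ANOVA and two-sided pooled-variance t-tests at α = 0.05.
* **Splits**: `segment_split()` takes the leading slices for training
  (90/30 by default); `random_split()` is the seeded uniform alternative.

## Numerical choices

* Tension-balance and recoil equilibria: bracketing + bisection
  (`uniroot`), tolerances $10^{-12}$ on tension and $10^{-10}$–$10^{-8}$
  mm on circumference; non-convergence raises an error with the residual.
* Angular unions are merged with a $10^{-9}$-degree tolerance; the
  per-edge subtended intervals assume deposits are radially compact
  (each edge subtends less than 180°), which densely sampled contours
  satisfy.
* Ray–polygon chord extraction treats tangential contacts by dropping
  unpaired intersections; rays are spread over the calcified union
  (3600 by default).
* Degenerate inputs: zero-area contours, non-positive stretches,
  infeasible deposit thicknesses, and empty training splits raise errors
  naming the offending slice where applicable.
* All randomness flows from explicit integer seeds; generation restores
  the caller's RNG state, so identical (config, seed) pairs are
  bit-reproducible.

## Problem sizes used in the checks

The packaged tests run the full 120-slice protocol where the design
depends on it (feature-structure correlations, subgroup comparisons, the
90/30 split) and 10–30-slice vessels for mechanics and IO round-trips.
The subgroup comparison aggregates eight replicate default-configuration
vessels, comparing mean per-vessel |bias| of the polynomial-kernel SVR:
single-vessel bias differences between feature groups are fractions of a
percent and noise-dominated, while the in-support error ordering
(all < stretch-only < calcification-only) is stable; averaging replicates
tests the same directional claim without widening any tolerance.

## Known limitations

* The surrogate has no contact, bending, axial coupling, calcification
  fracture, or tissue damage; the post-stenting lumen is assumed
  circular.
* The recoil model's wall-recovery term is a lumped, arc-fraction
  weighted idealization chosen for its direction and scale, not derived
  from continuum mechanics.
* Reported error statistics describe synthetic vessels; nothing here
  validates against measured post-stenting geometry.
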