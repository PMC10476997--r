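---
title: "Hypoxia-adapted ROWD planning: models, parameters and design choices"
author: "rowdplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypoxia-adapted ROWD planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowdplan)
```

## The problem

Hypoxic tumor subvolumes are substantially more radioresistant than
well-oxygenated tissue. The oxygen enhancement ratio (OER) quantifies this:
it is the ratio of the dose at a given partial oxygen pressure (pO2) to the
dose at a normoxic reference pressure producing the same biological effect.
In intensity-modulated proton therapy the biological effect additionally
depends on the dose-averaged linear energy transfer (LETd) through the
relative biological effectiveness (RBE). `rowdplan` combines the two into a
single photon-equivalent quantity — the RBE-and-OER weighted dose (ROWD) —
and optimizes pencil-beam spot weights until the ROWD is homogeneous over
the target. The optimizer consequently escalates physical dose (and, where
the geometry permits, LETd) precisely in the hypoxic subvolumes, a
voxel-level form of hypoxia dose painting that remains consistent with any
chosen RBE model.

## The OER model

Radiosensitivity under partial oxygenation is modeled with
linear-quadratic (LQ) parameters that interpolate between anoxic and
aerobic in-vitro fit constants with a half-saturation pressure
$K = 3$ mmHg:

$$\alpha(L, p) = \frac{(a_1 + a_2 L)\,p + (a_3 + a_4 L)\,K}{p + K},
\qquad
b(p) = \frac{b_1 p + b_2 K}{p + K},$$

with $L$ the dose-averaged LET in keV/µm and $p$ the voxel pO2 in mmHg.
The defaults are the in-vitro proton fit $a_1 = 0.10$ Gy⁻¹,
$a_2 = 0.0010$ µm/(Gy·keV), $a_3 = 0.010$ Gy⁻¹, $a_4 = 0.0100$ µm/(Gy·keV),
$b_1 = 0.765$ Gy⁻¹, $b_2 = 0.273$ Gy⁻¹. The OER at survival level
$s = 0.1$ is the ratio of 10%-survival doses,

$$\mathrm{OER}(L, p) =
\frac{D_{10}(\alpha(L,p), \beta(p))}{D_{10}(\alpha(L,p_a), \beta(p_a))},
\qquad
D_{10}(\alpha, \beta) = \frac{\sqrt{\alpha^2 - 4\beta\ln s} - \alpha}
{2\beta},$$

with reference pressure $p_a = 30$ mmHg. Two conventions relate $b(p)$ to
the quadratic LQ coefficient:

* **sqrt (default):** $\beta(p) = b(p)^2$. The b-constants are printed in
  Gy⁻¹, which are the units of $\sqrt{\beta}$, and the slab-phantom
  experiment below reproduces the expected hypoxic-dose escalation only
  under this reading. This is the package default.
* **linear:** $\beta(p) = b(p)$, i.e. the expression enters the $D_{10}$
  ratio directly. Available via
  `oerParams(betaConvention = "linear")` for sensitivity analyses.

Two rules bound the OER. Voxels at or above the normoxia threshold of
60 mmHg are treated as fully oxygenated with OER exactly 1. Between
$p_a$ and 60 mmHg the raw ratio dips marginally below 1; since the model
is never meant to *sensitize* tissue beyond the aerobic reference, the
OER is floored at 1 (`clampFloorOne`, default on).

```{r oer-curve}
p <- c(0.5, 2.5, 5, 11, 30, 60)
round(rbind(L0 = oer(0, p), L5 = oer(5, p)), 3)
```

## RBE models and hypoxic LQ parameters

Aerobic proton LQ parameters derive from the photon parameters
$(\alpha_x, \beta_x)$ of the irradiated structure — defaults
$(\alpha/\beta)_x = 10$ Gy for targets and 3 Gy for organs at risk — via
an RBE model:

* `constant_1p1`: $\alpha_{RBE} = 1.1\,\alpha_x$,
  $\beta_{RBE} = 1.1^2\,\beta_x$ (the clinical constant RBE);
* `MCN`: the published McNamara phenomenological fit,
  $RBE_{max} = 0.99064 + 0.35605\,L/(\alpha/\beta)_x$ and
  $RBE_{min} = 1.1012 - 0.0038703\sqrt{(\alpha/\beta)_x}\,L$, with
  $\alpha_{RBE} = \alpha_x RBE_{max}$ and
  $\beta_{RBE} = \beta_x RBE_{min}^2$;
* `ROR_approx`: a Rørvik-family model reduced to dose-averaged LET,
  $RBE_{max} = 1 + 0.645\,L/(\alpha/\beta)_x$ with unscaled $\beta$
  ($RBE_{min} = 1$). The full model weights the LET *spectrum*; the
  reduction to LETd is an approximation and is named accordingly.

Variable-model coefficients are never hard-coded: they ship in the
versioned JSON file `system.file("extdata", "rbe_coefficients.json")`
with a provenance note, and alternative files can be supplied to
`rbeModel()`.

Hypoxia scales these parameters through the OER:

$$\alpha_h = \alpha_{RBE} / \mathrm{OER}, \qquad
\beta_h = \beta_{RBE} / \mathrm{OER}^2 .$$

## The ROWD

For a voxel receiving proton dose $D_p$, total dose $D$ (protons plus
secondaries) and LETd $L$, the photon-equivalent ROWD inverts the LQ
effect:

$$D_{OER,RBE} = \frac{D}{D_p}\left(
\sqrt{\left(\frac{\alpha_x}{2\beta_x}\right)^2 +
\frac{\alpha_h D_p + \beta_h D_p^2}{\beta_x}}
- \frac{\alpha_x}{2\beta_x}\right).$$

With $\alpha_h = \alpha_x$, $\beta_h = \beta_x$, $D = D_p$ this is the
identity; with the constant RBE and OER = 1 the radicand is a perfect
square and the ROWD collapses to $1.1\,D_p$. Both identities are enforced
in the tests at $10^{-10}$ relative tolerance.

**Mixed fields.** LETd is accumulated per voxel from per-spot influence
data, $LET_{d,i} = \sum_j w_j n_{ij} / \sum_j w_j d_{ij}$ with
$n_{ij} = L_{ij} d_{ij}$, and $(\alpha_h, \beta_h)$ are evaluated once per
voxel at that LETd — matching the single-parameter-pair-per-voxel form of
the ROWD formula. The alternative spot-wise accumulation of
$\alpha_h D_p$ and $\beta_h D_p$ scores is a known variant but is not the
default here. The analytical engine transports primaries only, so
$D = D_p$ by default; a constant `secondaryFraction` $s$ sets
$D = D_p/(1-s)$ to exercise the mixed-field branch (how secondary dose
was voxelized in Monte-Carlo-based work is not derivable here, so a
constant fraction is an explicit stand-in).

## The analytical pencil-beam engine

Monte Carlo transport is out of scope; doses and LETd come from an
analytical engine whose constants live in `beamConfig()`:

* **Depth dose.** For residual range $t = R - z$ the pristine curve is
  $t^{1/p-1} + c\,t^{1/p}$ with the range–energy exponent $p = 1.77$ and
  plateau coefficient $c = 0.0047$ (entrance-to-peak ratio ≈ 0.3),
  convolved with a Gaussian of $\sigma = 2.2\%$ of the range (range
  straggling plus delivery energy spread) and re-anchored so the peak
  sits at the nominal range. Dose falls below 1% of the peak within the
  10 mm distal margin.
* **Depth LETd.** $L(z) = 1.1 + 40/(\max(R + 4 - z, 0) + 3)$ keV/µm,
  capped at 15: ≈1.5 at the entrance, ≈6–7 at the peak, 8–15 on the
  distal falloff — the voxel-scale depth-LETd morphology of published
  Monte Carlo proton pencil beams.
* **Lateral spread.** A depth-growing Gaussian,
  $\sigma(z) = \sqrt{2.2^2 + (0.035 z)^2}$ mm, integrated over voxel
  cross-sections; fields are axis-aligned (the slab-phantom geometry is
  coaxial, and axis alignment removes resampling ambiguity).

Influence matrices ($d_{ij}$, $n_{ij}$) are sparse with a per-spot
relative dose cutoff of $10^{-4}$; dose is exactly linear in the weights.

What the engine does *not* model: nuclear halo, range straggling fitted
to measured data, LET spectra (only LETd), secondary-particle transport,
CT-based stopping powers, non-axis-aligned fields. The main practical
consequence is that mixed-field LETd in regions dominated by stopping
protons saturates around 5–7.5 keV/µm, lower than Monte-Carlo-scored
distal-edge values; LET-escalation effects are therefore reproduced in
direction but compressed in magnitude (see Limitations).

## Initial plan and optimizer

`initSobpPlan()` lays a lateral spot lattice covering the target plus one
spacing of margin (default 5 mm spacing) and energy layers spanning the
target depth (default 4 mm range steps) — both free planning choices —
and flattens a constant-RBE 1.1 plan to the prescription with the same
optimizer, OER off: the standard clinical first approximation.

`optimizePlan()` then iterates, per iteration:

1. recompute the proton dose from the influence matrices (every
   iteration) and LETd, OER and $(\alpha_h, \beta_h)$ (every
   `letRefreshEvery` iterations, default 1);
2. evaluate the ROWD and the cost
   $\mathrm{mean}_{target}(R_i - P)^2 + \sum_c w_c\,
   \mathrm{mean}(\max(0, R_i - level_c)^2)$ — an unweighted quadratic
   target term plus one-sided quadratic organ-at-risk penalties (the
   default constraint level is the prescription itself);
3. update every spot weight multiplicatively,
   $w_j \leftarrow \max(w_{min}, w_j\,[\sum_i d_{ij} P_i^{eff} /
   \sum_i d_{ij} R_i]^{0.7})$, where $P^{eff}$ is the prescription on
   target voxels and the constraint level on currently violated
   constraint voxels. ROWD is nonlinear in the weights, so $R$ is treated
   as locally fixed per iteration (alternating recompute/update); the
   damping exponent 0.7 stabilizes that alternation.

Iterations stop when the relative cost change drops below `relTol`
(default $10^{-5}$) or at `maxIters` (default 200). Degenerate spots with
no accumulated ROWD over the objectives keep their weight (reported via a
warning); everything is deterministic, the configured seed is only
recorded in run manifests. A plain projected-gradient variant on the same
cost (exact ROWD dose derivative, backtracking line search) is available
via `optimizerConfig(method = "gradient")` and reaches the same target
coverage on the slab phantom.

## Fixture generators and what they emulate

`makeWaterPhantom()` builds the slabbed-oxygenation water phantom used
throughout: a 4×4×4 cm³ target at 8 cm depth on a 2 mm grid (8000 target
voxels), divided into seven equal slabs along the beam axis. The slab
pO2 values are the seven log-spaced values $2.5 \cdot 12^{k/6}$ mmHg,
$k = 0\ldots6$, arranged with the most hypoxic slab (2.5 mmHg) centered —
[30, 13.1, 5.7, 2.5, 3.8, 8.7, 19.8] proximal to distal — spanning the
severely hypoxic to mildly hypoxic range; the background is normoxic
water (160 mmHg, OER = 1 regardless). The phantom's outer dimensions
(60×60×160 mm³) are a configuration choice large enough to contain both
coaxial fields. Generation is pure: identical specs give identical grids.

`makeSyntheticCase()` emulates patient-like pO2 fields: a Gaussian random
field smoothed to a 10 mm correlation length and rescaled through its PTV
quantile so a requested fraction of PTV voxels falls below 60 mmHg — the
two bundled profiles being a severely hypoxic case (95% below threshold)
and a mildly hypoxic case (50%). It reproduces the *fraction and spatial
smoothness* of clinical hypoxia maps, not PET physics: no point-spread
function, noise, reconstruction artifacts, or uptake kinetics. Passing
tests on these fields demonstrate the optimizer's response to spatially
correlated hypoxia, not calibration against any imaging protocol.
`uptakeToPo2()` converts tracer-uptake grids through a pluggable monotone
calibration table (piecewise linear, clamped at the ends) — the
calibration curve itself is an input, not a package claim.

## Numerical choices

* OER is evaluated in closed form; the radicand
  $\alpha^2 - 4\beta \ln s$ is always positive since $\ln s < 0$.
* Histogram metrics use the ≥-threshold convention with no
  interpolation and a default 0.01 Gy bin (bit-stable `D50%`).
* `D(q)` is the largest bin edge still covering at least the fraction
  $q$ of the structure.
* Voxels with zero proton dose have ROWD and LETd 0 by convention.
* Grids must agree in dims, spacing and origin before any voxelwise
  operation; mismatches raise alignment errors rather than resampling.
* NIfTI I/O stores float32, RAS, mm, origin at the first voxel center.

## Problem sizes

The bundled experiments run on the 30×30×80-voxel phantom (2 mm
isotropic) with ≈900 spots per field, chosen to keep a full single-field
ROWD optimization around ten seconds on one core while resolving the
7 slab structure; the synthetic-case generator defaults to the same grid.

## Limitations

* The engine's voxel-scale LETd saturates near 5–7.5 keV/µm in
  high-dose regions, so LET escalation into hypoxic subvolumes is
  reproduced qualitatively (strictly above the constant-RBE reference)
  but peaks lower than Monte-Carlo-scored plans; LET-sensitive
  conclusions should be re-verified with a transport code.
* The ROR reduction to dose-averaged LET ignores spectrum shape; at the
  phantom's LETd range the approximation error is small relative to the
  OER effect but it is not bounded here.
* OAR handling supports maximum-dose constraints only — no mean-dose or
  DVH constraints, no robust optimization, no LET objective.
* In-vitro-derived constants (OER fit, RBE models) carry their usual
  translational uncertainty; the package propagates them, it does not
  validate them. `rowdSensitivity()` provides voxelwise derivatives of
  the ROWD with respect to pO2 and LETd for exploring this.
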