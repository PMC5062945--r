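---
title: "Estimating voxel-scale tumor oxygenation by multi-parametric image fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating voxel-scale tumor oxygenation by multi-parametric image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oxyfuse)
```

## The problem

Tumor hypoxia drives progression, metastasis and therapy resistance, but
pO2 cannot be mapped directly in vivo at useful resolution. Functional
imaging *can* map quantities causally linked to oxygen supply: perfusion
and fractional vascular volume (DCE-CT/MRI), and hemoglobin concentration
and saturation (photoacoustic and optical spectroscopy). `oxyfuse`
implements and validates a fusion approach: each imaging voxel is modeled
as a single effective cylindrical vessel (a modified Krogh cylinder), the
voxel's imaging-derived parameters become the model inputs, and the model
returns the voxel's mean pO2 (called MPO2).

Because no experiment provides simultaneous voxel-level imaging inputs
and ground-truth pO2, validation is by simulation: a detailed
Green's-function microvascular solver computes the reference tissue pO2
field from every vessel segment of a synthetic 3-D network (lattice
values LPO2, voxel averages GPO2), the imaging measurement is emulated by
reducing the in-voxel vascular architecture to effective inputs, and
MPO2 is compared with GPO2 voxel by voxel.

## The voxel model

In cylindrical coordinates around the effective vessel,

$$pO_2(r,z) = pO_2(0) \;-\; \frac{M H}{(1+m)F}\,G_2(z) \;-\;
  \frac{M H}{2 D}\,G_1(r),$$

with $M$ the oxygen consumption rate (µM/s), $H$ Henry's constant
(mmHg/µM), $D$ the tissue oxygen diffusion constant (µm²/s), $F$ the
perfusion per tissue volume (1/s), and $m = H C' \, dS/dP$ the local
slope factor of the Hill dissociation curve (the ratio of
hemoglobin-carried to dissolved oxygen release). The geometric form
factors follow from the classical Krogh–Erlang assumptions:

* radial diffusion with a sealed boundary at the tissue radius $r_T$:
  $G_1(r) = r_T^2 \ln(r/r_c) - (r^2 - r_c^2)/2$;
* an axial mass balance of blood oxygen content (dissolved plus bound,
  both linearized through $1+m$):
  $G_2(z) = (z/L)\,(1 - r_c^2/r_T^2)$.

These two forms are not arbitrary: with perfusion defined per voxel
volume they are the unique solutions of the radial ODE
$D\alpha\,(1/r)\,(r P')' = M$ (zero flux at $r_T$) and of the axial
advection balance $Q\,(1+m)/H \; dP/dz = -M \pi (r_T^2-r_c^2)$, and the
package's tests verify both against direct integration. The tissue
radius is $r_T = L/\sqrt{\pi}$ so the cylinder volume $\pi r_T^2 L$
equals the voxel volume $L^3$ (tissue mass is conserved). MPO2 is the
volume-weighted average of the pointwise solution over the annulus
$r_c \le r \le r_T$, $0 \le z \le L$ — in closed form when the field is
positive throughout, otherwise by 48-point Gauss–Legendre quadrature of
the zero-clamped field. By default the consumption rate is iterated
through the Michaelis–Menten law, $M \leftarrow M_0\,\mathrm{MPO2}/
(\mathrm{MPO2} + K_m)$, to 0.01 mmHg self-consistency; a constant-$M_0$
mode serves the pure-Krogh analyses.

The slope factor $m$ is evaluated once per voxel at the inlet pressure:
re-evaluating it locally would contradict the closed-form solution.
Negative model values are clamped at zero and flagged; clamped voxels
count as hypoxic in hypoxic-fraction analyses.

## Effective imaging inputs

For each half-open voxel $[o + iL, o + (i+1)L)$ the fusion stage derives
what imaging would measure:

* fractional vascular volume `fvv` = clipped vessel volume / $L^3$
  (exact line–box clipping);
* effective radius $r_c = L\sqrt{\mathrm{fvv}/\pi}$ — the radius of one
  voxel-spanning vessel of equal volume;
* effective perfusion $F = \sum_i Q_i\,\ell_i / (L\,L^3)$
  (path-length-weighted flow per voxel volume);
* voxel saturation $\mathrm{SaO_2} = \sum_i \mathrm{SaO_2}(i)\,
  \mathrm{vol}(i) / V$ over the contributing segments, with each
  segment's in-voxel saturation taken from the blood subsegment
  midpoints that fall inside the voxel;
* inlet pressure $P_{in}$ from the inverse Hill curve of the voxel
  saturation, and $m$ at $P_{in}$.

The radius and perfusion definitions were chosen so that a single
straight vessel spanning its voxel is reproduced exactly; the tests
assert this reduction. Voxels without vasculature are invalid and are
excluded from regressions (they can optionally be filled by the
nearest-neighbor correction).

## The reference solver

The reference field treats every vessel subsegment (50 µm target length)
as an oxygen source and every 15 µm lattice point as a Michaelis–Menten
sink:

$$P(x) = \sum_j q_j G(x - x_j) - \sum_k M(P_k)\,h^3\,G(x - y_k),
\qquad G(r) = \frac{1}{4\pi D \alpha\, \max(r, h/2)}.$$

Subsegment sources use the exact uniform finite-line kernel (sharper
near field, identical far field). The release rates $q_j$ are determined
by matching the tissue pO2 at each subsegment's wall (perpendicular
distance $r_c$) to the intravascular blood pO2, which declines along
each flow path as content $\alpha_b P + C' S(P)$ is released; branching
networks mix content at nodes by flow fraction. The coupled nonlinear
system in (tissue field, release rates) is solved by a globalized Newton
iteration: matrix-free BiCGSTAB linear solves with FFT evaluation of the
sink convolution, the exact linearized blood march as the blood-side
Jacobian block, and a line search. Voxel GPO2 values are means of the
in-domain lattice points falling in each voxel.

Numerical choices that matter:

* **Tissue margin.** The network domain is embedded in consuming tissue
  extending 75 µm beyond the domain box (150 µm where guard vessels sit
  near the boundary), covering the oxygenation halo so that, at steady
  state, total release balances total consumption inside the lattice to
  well under 1 %. The superposition kernel itself is free-space (open
  boundary), so an insufficient margin shows up honestly as a balance
  gap rather than being hidden by the discretization.
* **Smoothed switching.** The Michaelis–Menten sink crosses zero through
  a C¹ ramp of 0.1 mmHg width, and blood content through a 40 µM ramp;
  anoxic tissue and fully depleted branches then carry exactly zero
  consumption/release while the Newton iteration stays differentiable.
* **Tolerances.** The regular fixtures converge to a maximum equation
  residual of 0.01 mmHg. The stochastic tree networks are run at
  0.75 mmHg: collocation rows of subsegments crowded around branch
  nodes retain residuals of that order, while the field away from those
  points is far more accurate; the conservation diagnostic (≈0.1–0.2 %)
  is unaffected.
* **Oracle.** An independent finite-difference solver (second-order,
  sealed boundaries, red-black SOR with a global-balance deflation,
  the same blood-marching physics, ring-sampled wall matching with an
  analytic continuation to the wall radius) reproduces the superposition
  field to ≈0.5 mmHg interior RMS on the single-vessel and
  four-vessel fixtures — points within two lattice spacings of a vessel
  axis are excluded because the two discretizations represent the
  sub-lattice singular field differently.

## Study fixtures: what they emulate, and what they do not

The original window-chamber microvascular datasets behind the study are
not redistributable, so the package generates synthetic stand-ins:

* `krogh` — one capillary (radius 5 µm, flow 2×10⁵ µm³/s, inlet
  saturation 0.9) spanning a 120 µm tissue cube. The cube is sized so a
  single capillary fully oxygenates it at the tumor consumption rate —
  the regime in which the Krogh solution is valid. The Krogh-limit
  acceptance comparison seals this cube (margin 0) because a sealed
  voxel *is* the model's boundary assumption; in open tissue the same
  vessel also feeds its surroundings and the voxel average necessarily
  sits below the model's.
* `parallel` — a capillary bed at 50 µm spacing (a typical
  inter-capillary distance) with per-vessel heterogeneity in radius and
  flow and a smooth spatial gradient of inlet saturation, emulating
  capillaries fed by shared arterioles. A 6×6 array is generated but
  only the interior 200×200×200 µm block around the central 4×4 vessels
  is measured; the outer ring and the axial continuations are guard
  bands that supply the surrounding tissue, so the interior behaves
  like a periodic, well-supplied bed (normal tissue at imaging
  resolution).
* `tumor` — stochastic tortuous branching trees grown by a reflected
  biased random walk in the 990×810×150 µm window-chamber slab, radii
  3–15 µm tapering root-to-tip, ~2 % vascular volume, hemodynamics from
  a Poiseuille solve rescaled to a total inflow of 230.37 nL/min.
  Inter-vessel spacing spans roughly 12–125 µm, producing the
  characteristic mix of well-perfused cords and hypoxic pockets.
* `brain` — the same generator in a 150×160×140 µm block with finer,
  denser vessels, inflow 10.8 nL/min and the brain consumption rate.

What passing tests on these fixtures show is that the fusion model
tracks a detailed reference *when its structural assumptions
approximately hold* and degrades at coarse voxels exactly as the
underlying physics predicts. They do not show performance on real
microvasculatures: real networks have counter-current pairs, correlated
hematocrit heterogeneity, and measured (not Poiseuille) flows, none of
which the generator reproduces. Quantities that depend on the specific
network realization — regression slopes at a given voxel size,
sensitivity percentages, CV values — should be read as qualitative
analogues, not reproductions, of the published study values.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `M0` (tumor) | 0.0004 cm³O₂/cm³/s → 17.86 | µM/s | maximum consumption |
| `M0` (brain) | 0.0025 cm³O₂/cm³/s → 111.6 | µM/s | maximum consumption |
| `C_prime` | 8800 | µM | saturated Hb O₂ capacity |
| `n_hill`, `P50` | 3.0, 26 | –, mmHg | Hill curve |
| `H` | 0.74 | mmHg/µM | Henry constant |
| `D` | 2000 | µm²/s | tissue O₂ diffusion |
| `Km` | 1.0 | mmHg | Michaelis–Menten half-rate pressure |
| lattice `h` | 15 | µm | reference lattice spacing |
| subsegment `ds` | 50 | µm | source discretization |
| voxel sizes | 50–300 (tumor), 50–100 (brain) | µm | imaging sweep |
| grid offsets | 5 for L ≥ 200 µm, else 1 | – | translation ensemble |
| HF thresholds | 2.5–15 (tumor), 16–22 (brain) | mmHg | HF ladders |

`Km` deserves a flag: it is not part of the published constant set; the
1 mmHg default is the value conventionally used with Michaelis–Menten
oxygen sinks in microvascular transport models, and the hypoxic tail of
the reference solution is sensitive to it. It is exposed in
`physiology_params()`. Unit conversion of O₂ volume fractions uses the
STP molar volume 22,400 cm³/mol. Blood solubility is taken as $1/H$;
the alternative mass-based solubility tag is accepted by
`to_canonical_units()`. Hemoglobin capacity uses $C'$ directly, without
per-segment hematocrit scaling, mirroring the single-value convention
of the constant set; inlet saturations default to 0.9 (arteriolar).

## Design choices on genuinely open points

* **Nearest-neighbor correction.** The correction exists to absorb
  oxygen exchange between adjacent fine voxels. Two published-style
  variants exist: replacing a voxel by its face-neighbors' mean, or
  averaging the voxel together with its neighbors. The package provides
  both; `"augment"` (include the voxel itself) is the default because
  on the synthetic tumor fixture pure replacement destroys as much
  signal as it recovers, while augmentation improves the 50 µm
  correlation as intended. Filling vessel-free voxels from their
  neighbors is available (`fill_invalid = TRUE`) but off by default for
  the same reason.
* **Sensitivity scan.** One input at a time is scaled by ±10 % and
  ±20 % across the voxel ensemble of a fusion run and the percent
  change of the mean MPO2 recorded. Scaled saturations are re-clipped
  at a physiological ceiling of 0.99 (the inverse Hill transform
  diverges as S → 1). The magnitude ordering beyond the robust
  statements (consumption dominates; radius effects exceed nothing that
  matters more) is strongly network-dependent.
* **Error propagation.** Per voxel, mock measurements are drawn from a
  Gaussian with FWHM equal to 20 % of the measured value
  (σ = FWHM/√(8 ln 2) ≈ 8.5 % relative); non-positive draws are redrawn
  rather than clamped to keep the input mean unbiased. Per-voxel
  replicate streams derive deterministically from (seed, voxel index),
  so results do not depend on evaluation order.
* **Grid placement.** The first ensemble member is always the
  untranslated grid; further members draw offsets uniformly from
  (−L/2, L/2)³ with a seeded RNG.

## Problem sizes

The reference solves in the tests and the reproduction script use the
full study geometries: the 990×810×150 µm tumor slab at the 15 µm
lattice (≈10⁵ points, ≈480 subsegment sources; a few minutes), the
capillary bed (≈14–39 k points; seconds), and the single-vessel cube
(seconds). The finite-difference oracle runs at 5–15 µm spacing on the
small fixtures only.

## Known limitations

* Steady state only; acute (cycling) hypoxia requires the
  time-dependent extension the model family anticipates but this
  package does not implement.
* Single-vessel voxels: no multi-vessel analytic voxel is provided, so
  accuracy degrades for voxels much larger than the inter-vessel
  spacing — that degradation is itself one of the validated findings.
* The free-space superposition with a finite consuming margin leaks a
  small flux out of the lattice; with the default margins this is
  ≪1 % of the release, but configurations with vessels near the
  lattice edge will show it in the conservation diagnostic.
* Wall collocation at crowded branch points limits the tree-network
  residual to ~1 mmHg at isolated subsegments.
* No Bohr-effect corrections to P50, no myoglobin, no vessel-wall
  oxygen permeability, no radius-dependent blood viscosity.
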