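---
title: "Mechanobiological scaffold design optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanobiological scaffold design optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scaffopt)
```

`scaffopt` simulates endogenous bone regeneration inside a 3D-printed,
pore-graded cylindrical scaffold implanted in a critical-size long-bone
defect, and searches the scaffold's pore-size design space for the geometry
that maximizes the regenerated bone volume fraction in the scaffold pores at
24 weeks. This vignette explains the models, their assumptions, the tunable
parameters, and the design choices made where the underlying methods left
the design genuinely open.

## The design problem

The scaffold is an annular cylinder (outer radius 10 mm, inner radius 5 mm,
height 40 mm — the defect length) carrying square-section pore channels
along three perpendicular directions. Three parameters describe the pore
architecture:

* `x1` — horizontal pore size nearest the bone extremities (mm),
* `x2` — horizontal pore size at scaffold mid-height (mm), with a linear
  gradient over the rows between,
* `x3` — side of the 12 square vertical channels (mm).

`x1` and `x2` range over [0.3, 3.8] mm and `x3` over [0.3, 3.0] mm. The
lower bound reflects the minimal pore size compatible with vascularization
and nutrient supply; the upper bounds prevent adjacent pores from merging
outright.

### Pore layout: the calibrated interpretation

The source geometry leaves the horizontal pore layout ambiguous: a stated
1 mm center spacing is geometrically incompatible with pore sizes up to
3.8 mm and with the stated no-overlap rationale for the upper bound. The
package therefore treats the layout as a calibrated model with two fixed
conventions, chosen once so that the voxelized geometry reproduces the
macroscopic porosities of the six independently reported reference designs
(85, 84, 71, 29, 24 and 22 %) within ±2 percentage points:

* horizontal channels run **radially** through the annulus wall, arranged
  around the circumference with a **2.2 mm center pitch** measured at the
  mid-wall radius (21 channels per row);
* each half scaffold carries **5 rows** centered on equal vertical bands
  (row centers at `(k + 0.5) H / 10`), mirrored about mid-height, so the
  two `x2` rows flank the symmetry plane.

With this layout, large pores (above the ~2.2 mm pitch) merge
circumferentially into slot-like openings — which is what makes the highly
porous reference designs (~85 %) and the weakly porous ones (~22–24 %)
simultaneously reproducible; a wider pitch reproduces neither. Both
conventions are configurable in `scaffold_spec()`.

Geometry is voxelized by cell-center membership (constructive solid
geometry by membership test rather than exact booleans). Porosity is the
count of pore voxels inside the hollow-cylinder envelope times the voxel
volume, over the analytic envelope volume. At the production voxel edge of
0.05 mm the porosity is converged to well under one percentage point (the
refinement tests assert `|p(h) - p(h/2)| < 0.01`).

## The regeneration simulator

A run couples two models daily, for 168 days (24 weeks):

### Voxel finite-element mechanics

The half domain (mid-height symmetry) contains the scaffold with its pores,
the callus envelope (an arc of revolution, 10 mm maximal width at
mid-height, overlapping the intact bone by 10 mm), the intact cortical tube
and the marrow cavity. Mechanics are solved on a structured grid of cubic
trilinear hexahedral elements (aggregated voxels; 1.2 mm elements at full
scale, matching the callus mesh scale of comparable models). Element
properties follow a rule of mixtures — the arithmetic mean of the material
cards of the agent sites the element contains — further averaged over the
last ten days (a ring buffer) to represent the time tissue needs to deposit
and mature.

The load case is a 1372 N axial compression plus a 17.125 N·m
anterior-posterior bending moment applied as statically equivalent nodal
forces on the proximal cortical face. The internal fixation hardware (plate
and screws) is not meshed; it is abstracted as grounded springs on the
proximal face (default 2000 N/mm axial, 500 N/mm lateral — the order of
locking-plate constructs used in large-animal tibia models). Because the
mid-height symmetry plane constrains axial displacement, a grounded axial
spring at the loaded face is exactly the plate's load path towards the
mirrored half. The symmetry plane carries a zero-normal-displacement
condition. The sparse symmetric system is solved by a Cholesky
factorization (CHOLMOD), which is exact and deterministic; an iterative
solver adds a tolerance parameter without buying anything at these problem
sizes (a few thousand to ~10^5 unknowns).

From the element strains the simulator derives the two mechanoregulation
inputs: the octahedral shear strain
\(\gamma = \tfrac{2}{3}\sqrt{(\varepsilon_1-\varepsilon_2)^2 +
(\varepsilon_2-\varepsilon_3)^2 + (\varepsilon_3-\varepsilon_1)^2}\)
and an interstitial fluid speed \(\nu\). The fluid speed uses a single-step
consolidation estimate: pore pressure proportional to volumetric strain via
the fluid bulk modulus (`p = -K_f tr(eps)`), Darcy flux
\(\nu = k\,|\nabla p|\) by central differences on the element grid, drained
(`p = 0`) outer boundaries, no-flow mirrors at the symmetry plane and at
impermeable (scaffold) neighbours. A transient poroelastic solve would add
a time-integration scheme the daily coupling never samples; the one-step
estimate is the package's choice and is recorded in the output metadata
(`scheme = "darcy"`; a volumetric-strain-rate proxy is available as
`"strain_rate"`).

### Mechanoregulation

The scalar stimulus is \(S = \gamma/a + \nu/b\) with the empirical
normalizers \(a = 0.0375\) (dimensionless) and \(b = 0.03\) mm/s. Stimulus
bins select the locally favored tissue: resorption below 0.01, mature bone
to 0.53, immature bone to 1, cartilage to 3, fibrous tissue above. The
source thresholds are written with strict inequalities on both sides, which
leaves the boundaries unassigned; the package closes each bin on the left
(half-open intervals), a measure-zero convention that makes classification
total.

### Agent-based cellular model

Each lattice site (100 µm at full scale) holds at most one agent:
progenitor cell, fibroblast, chondrocyte, or immature/mature osteoblast,
with the associated matrix (granulation tissue, fibrous tissue, cartilage,
immature/mature bone). The daily event order is fixed (and config-
documented, since the original publication does not state it): resorption,
migration, differentiation, proliferation/apoptosis, material update.

* **Seeding** — progenitors occupy marrow sites and periosteal sites
  (callus sites within one site layer of the cortical surface) with 30 %
  probability each, independently.
* **Migration** — progenitors walk at 30 µm/h: 7.2 expected lattice steps
  per day at 0.1 mm sites, the fractional step realized by stochastic
  rounding (7 steps with p = 0.8, 8 with p = 0.2); each step moves to a
  uniformly chosen empty 6-neighbour or stays when blocked. Movement uses
  the 6-neighbourhood (metric moves); surface sensing uses the
  26-neighbourhood (deposition follows surfaces broadly).
* **Differentiation** — a progenitor adjacent (26-neighbourhood) to an
  existing surface (scaffold, cortical bone, or non-progenitor tissue)
  converts at 0.3/day to the phenotype of its stimulus bin; the resorption
  bin triggers no differentiation.
* **Proliferation / apoptosis** — a cell in its favorable bin duplicates
  into a uniformly chosen empty neighbour with probability 0.60, 0.55,
  0.20, 0.30 per day (progenitor, fibroblast, chondrocyte, osteoblast);
  otherwise it dies with probability 0.05, 0.05, 0.10, 0.16. The favorable
  bins per phenotype are not tabulated in the source; the package aligns
  them with the classification: osteoblasts in either bone bin,
  chondrocytes in the cartilage bin, fibroblasts in the fibrous bin,
  progenitors anywhere above resorption.
* **Graft stimulation** — graft material is assumed present in the pores,
  where it multiplies proliferation and differentiation probabilities by
  `graft_factor` (default 2, probabilities capped at 1). The magnitude is
  unstated in the source and exposed as configuration.
* **Resorption** — osteoblasts below the resorption threshold are removed;
  the source does not say whether removal is instantaneous or gradual, so
  the daily removal probability is configurable (default 1).

The outcome is the **bone volume fraction in the pores**: osteoblast-
occupied pore sites (both phenotypes) over all pore sites.

All stochastic kernels draw from R's RNG (also inside the C++ hot loops),
so a run is bit-reproducible from `(config, seed)`.

## Surrogate optimization

A full-scale regeneration run is expensive, so the optimizer never touches
it directly. The framework:

1. evaluates the regeneration oracle on a Latin hypercube sample (20 x the
   number of design variables = 60 points; `lhs::randomLHS`, one point per
   stratum per marginal);
2. fits a DACE-style kriging surrogate: constant trend, exponential
   auto-correlation `R(d) = exp(-sum theta_k |d_k|)` over unit-cube
   normalized inputs, correlation lengths by profile-likelihood maximum
   likelihood (8-start L-BFGS-B over `log theta` in `[0.01, 20]`, nugget
   1e-8 — small enough to preserve interpolation to ~1e-6);
3. maximizes the surrogate with one of three bounded global optimizers —
   Hooke-Jeeves pattern search from the fixed start (2.05, 2.05, 1.65) mm,
   a generational GA (population 50, 50 generations, tournament selection,
   blend crossover, Gaussian mutation, elitism 2), or global-best PSO
   (population 30, 100 iterations, inertia 0.729, c1 = c2 = 1.49445);
4. verifies the candidate with the oracle, and loops:
   * **loop 1** until surrogate prediction and oracle agree within 0.05
     *absolute* on the bone-fraction scale (the source's "max 5%
     discrepancy" could be absolute or relative; absolute is the default,
     relative is a config switch), each verified point enriching the
     dataset;
   * **loop 2** until a verified optimum is at least as good as every
     stored oracle value (tolerance 1e-6, hard cap of 30 extra calls),
     guarding against local optima of the surrogate.

Every oracle call lands in an append-only ledger (design, objective,
provenance, seed, call index). The ledger deliberately records a call index
instead of wall-clock time: the package guarantees bit-identical ledgers
for identical `(config, seed)`, which a timestamp would break. The reported
optimum is always oracle-verified, never a surrogate value.

Two analytic toys with known optima (`toy_oracles()`) exercise the loop
end-to-end: a concave quadratic (maximum 0.9 at (2, 2, 1.5)) and a
two-basin objective with equal global maxima. On the quadratic the
framework converges to within 0.02 of the analytic maximum with a final
loop-1 discrepancy at or below the 0.05 tolerance. One measured caveat: on
a smooth function the exponential (non-differentiable) kernel needs the
full 60-point design to cross-validate below 5 % of range — at 30 points
its leave-one-out floor is about 6.6 % regardless of the correlation
lengths — so the cross-validation checks run at the framework's actual
design size.

## Scaled-down study conditions

Tests and in-loop oracles cannot run the full-scale model (0.1 mm sites,
~10^8 voxels, 168 daily FE solves), so the package defines two presets in
`scaffopt_config()` whose problem sizes are the package's own choices:

* **desk** — half linear scale (outer radius 5 mm, height 20 mm, callus
  width 5 mm), 0.2 mm sites, 2 mm elements, pore sizes halved with the
  geometry, and loads scaled to preserve nominal stresses (axial 1372/4 N,
  moment 17.125/8 N·m, since area scales with 1/4 and section modulus with
  1/8). About 7.5 x 10^5 sites.
* **micro** — desk geometry at 0.4 mm sites, 2.4 mm elements, 28-day runs;
  used where the regeneration oracle sits inside an optimization loop. The
  optimization-in-the-loop checks additionally shrink the design of
  experiments to 24 points and cap each verification loop at 6 extra
  oracle calls — sizes chosen for the micro oracle, not the full study.

What the desk fixture preserves: the coupling structure (FE -> stimulus ->
cell events -> materials -> FE), the stimulus magnitudes (via the
stress-preserving load scaling), the full rule set at its printed rates,
and the qualitative material contrast — a titanium scaffold at a mid-range
design reaches a high pore bone fraction (~0.96 after 168 desk days) while
the same design in a granulation-soft material yields essentially none,
mirroring the stiffness contrast of the full-scale study. What it does not
preserve: absolute pore-size-to-cell-size ratios, vascular limitations
(absent from the model altogether), fixation-hardware geometry, and the
quantitative bone fractions of the full-scale model — which is why the
package's acceptance checks treat full-scale regeneration percentages as
out of reach and verify stage-level physics and sign-level contrasts
instead.

## Numerical choices and degenerate inputs

* Voxel membership is cell-centered; ties at region boundaries resolve by
  assignment order (scaffold overrides callus, pores override scaffold).
* Elements are active when at least half their voxels are in-domain;
  floating (disconnected) element components are a hard error naming the
  component.
* The patch test holds to machine precision: a homogeneous prismatic
  domain under consistent axial loading reproduces `F/(EA)` exactly, since
  the uniform-strain field lies in the trilinear element space.
* Kriging refuses fewer than `d + 2` points and degenerate (constant-
  dimension) designs; duplicate candidate designs are jittered by one
  correlation-length-scaled step before oracle evaluation.
* A zero-day run returns bone fraction 0 (pores seed empty); a zero-length
  defect yields a domain without scaffold or callus.
* `classify_stimulus(0)` is RESORPTION; negative stimulus inputs are
  validation errors, not clamps.

## Known limitations

* Vascularization, oxygen transport and scaffold degradation are not
  modelled (stated limitations of the source model; degradation is its
  named future work).
* The fixation abstraction shares load with the tissue column; its
  stiffness defaults are literature-scale, not calibrated to a specific
  construct. Under very soft tissue columns the springs carry most of the
  load (stress shielding), which is physically expected but means the
  absolute stimulus in an empty defect depends directly on this setting.
* The pore-layout conventions (radial channels, 2.2 mm pitch, band-centered
  rows) are one consistent reading of an ambiguous description, validated
  against the six printed porosities; other readings reproduce fewer of
  them.
* Mechanics elements aggregate ~10^3 agent sites; tissue composition within
  an element is homogenized, so thin tissue layers are smeared over the
  element volume.

## Reproducing the study figures

```{r, eval = FALSE}
# porosity of a printed reference design
scaffold_porosity(scaffold_design(3.12, 3.26, 2.64), voxel_edge = 0.05)

# one desk-scale regeneration run, histology-style section
out <- run_regeneration(scaffold_design(2.05, 2.05, 1.65), "titanium",
                        scaffopt_config("desk"), seed = 1)
autoplot(render_histology(out))

# the full framework on the micro oracle
res <- run_framework(mbbr_oracle("titanium", scaffopt_config("micro")),
                     optimizer_config("particle_swarm", seed = 1))
autoplot(res)
porosity_bone_scatter(res$ledger, design_scale = 0.5)
```
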