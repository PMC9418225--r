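---
title: "Multiscale perfusion and bioheat modeling with hemotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale perfusion and bioheat modeling with hemotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemotherm)
```

## The model

`hemotherm` simulates steady blood flow and heat transport in a labeled
voxel domain containing segmented arterial and venous trees. Three scales
are coupled:

1. **Resolved vessels (1-D).** Each tree is a graph of pressure nodes and
   cylindrical elements; laminar element flow is
   $q = \kappa\,\Delta p$ with $\kappa = \pi R^4 / (8 \mu L)$. Roots carry
   Dirichlet pressures ($P_{in}$ for arteries, $P_{out}$ for veins);
   internal nodes carry Kirchhoff mass balances. Flow direction is a
   result, not an input: element flows are signed.

2. **Tissue continuum (3-D).** Every tissue voxel holds two pressures,
   one per capillary-bed compartment. Cross-voxel flow follows Darcy's
   law, discretized with two-point flux approximation: face
   transmissibility $t = A\,\bar k/(\mu\,ds)$ with the harmonic mean
   $\bar k$ of the side permeabilities (uniform-permeability domains are
   unaffected by the averaging choice; a zero permeability seals the
   face). Intra-voxel perfusion from arterial to venous compartment is
   $u_{perf} = \alpha (P_a - P_v)$, a volumetric rate density (1/s): the
   printed unit of $\alpha$, m s kg$^{-1}$, is dimensionally
   Pa$^{-1}$s$^{-1}$, which is what makes $\alpha \Delta P\,V$ a voxel
   volumetric rate. Per-voxel source/sink rates are stored as absolute
   rates (m$^3$/s); densities are available by dividing by the voxel
   volume.

3. **Terminal coupling (the sphere of influence).** A terminal's flow is
   spread over the tissue voxels within distance $\varepsilon$ of the
   terminal node by the compact bump
   $\eta(x) = C \exp(1/(|x|^2-1))$ for $|x|<1$, scaled by
   $\eta^\varepsilon(x) = \eta(x/\varepsilon)/\varepsilon^n$. The
   constant $C$ is calibrated **per terminal against the discrete
   voxel-center quadrature**, so the weights
   $w_{k,i} = \eta^\varepsilon(x_i - x_k) V_i$ sum to one exactly even
   where the sphere is clipped by the domain boundary — otherwise mass
   would leak from the virtual unresolved network precisely where
   clipping occurs. Because of this discrete calibration the nominal
   dimension $n$ only rescales $C$ and never changes a weight; we take
   $n = 3$. Terminal flow and tissue pressure are tied by the continuity
   relation $q_k = (\gamma/\mu)\,(p_k - \sum_i w_{k,i} P_i)$, where
   $\gamma$ is the pressure-drop parameter of the virtual network. At the
   reference value $\gamma = 10^{14}$ m$^3$ the virtual resistance
   $\mu/\gamma$ is negligible, so the terminal nodal pressure tracks the
   weighted local tissue pressure; users changing $\gamma$ by orders of
   magnitude are changing the virtual-network resistance accordingly.

Vessel-labeled voxels are hydraulically inert (resolved vessel flow is
carried entirely by the 1-D network; blood cannot permeate a vessel wall)
and have no independent thermal unknowns: each belongs to exactly one
element, and all member voxels of an element are isothermal with it.

### Heat transport

The thermal unknowns are one temperature per tissue voxel and one per
vessel element. Steady-state voxel balances sum, over the six faces,
overall heat-transfer coefficients in series-resistance form
($U = K_t/ds$ between tissue half-cells,
$U = [ds/2K_t + 1/h_\infty]^{-1}$ against ambient air,
$U = [ds/2K_t + 1/h_b]^{-1}$ across a vessel wall, with $ds$ the
axis-aligned center distance of the face — anisotropic grids use the
spacing of the face axis), plus advection and metabolic generation.
Advection uses the difference form $\dot m c_{p,b}(T_{up} - T_{local})$
restricted to inflows (donor-cell upwinding); the outflow enthalpy at the
local temperature cancels through mass closure, which the package checks
against the flow residuals before assembly. Inter-voxel advected mass
sums both compartments' face flows, because the voxel is a single thermal
node (blood and tissue in a voxel are at thermal equilibrium, and
intra-voxel perfusion between the compartments carries no heat).
Mollifier sources deliver blood at the supplying terminal **element**
temperature; no heat loss is modeled along the virtual vessels. Element
rows balance along-tree advection (merging nodes blend their inflows
proportionally to the outflow split) and wall convection; arterial root
elements are pinned to $T_{in}$, and the venous root is a purely
advective outlet with no thermal Dirichlet condition.

One deliberate deviation from the usual presentation: the wall
coefficient $[ds/2K_t + 1/h_b]^{-1}$ is applied on **both** sides of each
tissue–vessel contact face. Using the bare film coefficient $h_b$ on the
element side while the voxel side carries the series coefficient would
make the two halves of the same interfacial flux unequal and the scheme
non-conservative; with the bundled $h_b$ values the coefficient
difference is below 0.1%, but the energy audit would never close to
round-off. Conservation of the assembled equations is the property this
package treats as non-negotiable, since the solver's convergence metric
(the maximum absolute equation residual, in watts) *is* an
energy-conservation discrepancy.

Blood thermal conductivity $K_b$ appears in the reference parameter set
but in no equation of the element balance (advection plus wall
convection); it is parsed and reported unused.

The vessel-wall coefficient switches the physical regime:
`mode = "pbm"` ($h_b = 0.001$ W m$^{-2}$ °C$^{-1}$) reproduces the
Pennes-type assumption — the arterial tree is isothermal at the inlet
temperature and every directly sourced voxel receives blood at $T_{in}$
regardless of distance; `mode = "wjm"` ($h_b = 10$) activates
counter-current exchange — arterial blood cools toward the terminals and
venous return is pre-warmed by the tissue.

## Parameters

| key | meaning | unit | default |
|---|---|---|---|
| `k_a`, `k_v` | compartment permeability | m² | 1e-12, 5e-10 |
| `alpha` | compartmental perfusion coefficient | Pa⁻¹ s⁻¹ | 1e-6 |
| `mu` | blood viscosity | Pa s | 3e-3 |
| `gamma_a`, `gamma_v` | virtual-network pressure-drop parameter | m³ | 1e14 |
| `P_in`, `P_out` | root pressures | Pa | 10600, 1600 |
| `epsilon` | sphere-of-influence radius | m | geometry-calibrated |
| `K_t` | tissue conductivity | W m⁻¹ °C⁻¹ | 0.49 |
| `c_pt`, `c_pb` | specific heats (tissue, blood) | J kg⁻¹ °C⁻¹ | 3421, 3617 |
| `rho_t`, `rho_b` | densities | kg m⁻³ | 1090, 1050 |
| `qdot_m` | metabolic generation | W m⁻³ | 0 |
| `h_b` | vessel-wall convection | W m⁻² °C⁻¹ | 0.001 (pbm) / 10 (wjm) |
| `h_inf` | ambient convection | W m⁻² °C⁻¹ | 20 |
| `T_in`, `T_inf` | inlet / ambient temperature | °C | 35, 20 |
| `tol` | linear-solver relative residual | — | 1e-8 |

The defaults are the reference parameter set for an amphibian-tongue
scale domain with 64 × 64 × 333 µm voxels; metabolic generation defaults
to zero because cold-blooded tissue at desk scale generates negligibly.
The default solver tolerance of 1e-8 follows the published convergence
study for this model class, where the maximum equation residual at that
tolerance is already far below any physically meaningful power.

## Synthetic fixtures and what the tests show

`make_darcy_slab()` builds a 1×1×n tissue slab whose TPFA solution is
*exactly* the linear continuum profile — it validates the face
discretization and nothing else. `make_single_vessel_slab()` builds a
straight artery / tissue / counter-current vein sandwich; with a single
tissue voxel the total flow has a closed series-resistance form
$1/\kappa_a + \mu/\gamma_a + 1/(\alpha V) + \mu/\gamma_v + 1/\kappa_v$
used as an oracle, and the multi-element variant orders arterial elements
along the flow for the counter-current temperature checks.
`make_three_layer_toy()` is a miniature analogue of a planar organ
converted to three layers (arterial tree / pure tissue / venous tree, so
sources must perfuse across the middle layer to reach the sinks), with
Murray-type radius tapering, ±10% seeded radius jitter, and a
sphere-of-influence radius calibrated to 1.05× the largest
nearest-terminal distance, the smallest radius that guarantees every
tissue voxel at least one direct source and one direct sink — the
coverage property the reference configuration states.

These fixtures exercise conservation, boundedness, monotonicity,
closed-form agreement, solver equivalence and regime switching. They do
**not** emulate tortuous anatomical vasculature, heterogeneous
permeability maps, stair-step boundary effects of segmented organ
outlines, or domain sizes where preconditioner quality dominates; passing
tests therefore validate the discretization and solvers, not the fidelity
of any particular organ model.

## Numerical choices

* **Ordering.** Voxels are linearized in R's native array order (x
  fastest), 1-based; unknowns are ordered `[P_a; P_v; p_arterial;
  p_venous; q_terminal]` for flow and `[T_tissue; T_element]` for heat.
  Matrix row order is fixed and reproducible.
* **Terminal flows as explicit unknowns.** Substituting the continuity
  relation into the voxel equations multiplies mollifier weights by
  $\gamma/\mu \sim 3\times10^{16}$ and annihilates the Darcy
  transmissibilities ($\sim 10^{-13}$) in double precision. Keeping
  $q_k$ as unknowns, with the continuity row scaled by $\mu/\gamma$,
  yields the same algebra with order-one row coefficients.
* **Equilibration and refinement.** Every solve path works on a
  Ruiz-equilibrated copy (iterated row/column inf-norm scaling). The
  direct (sparse LU) and dense paths add two steps of iterative
  refinement; the GMRES path (restarted, modified Gram–Schmidt, Givens
  rotations, right-preconditioned by a hand-rolled CSR ILU(0) in
  compiled code) adds outer refinement with corrections solved two
  orders tighter than the requested tolerance. The flow system's
  condition number is intrinsically large — the physics couples
  conductances from $\mu/\gamma$ to $\alpha V$ spanning many decades —
  and a single Krylov solve at 1e-8 leaves correlated errors; with
  refinement the GMRES path matches the dense oracle at desk scale.
  Unpreconditioned GMRES stalls on these systems and is provided only
  for experimentation.
* **Heat in offset variables.** The thermal system is assembled in
  $\theta = T - T_\infty$; the ambient right-hand side vanishes and,
  with zero metabolic generation, the whole field is exactly
  proportional to the inlet offset. This makes the sensitivity identity
  $\bar X_{\theta_{in}} = 1$ hold to solver precision rather than
  approximately.
* **Degenerate inputs.** Equal root pressures give an exact quiescent
  equilibrium; a zero-flow solution yields an empty advection graph;
  $h = 0$ seals a face rather than erroring; a terminal whose sphere of
  influence contains no tissue voxel raises an error naming the
  terminal (the radius is too small for the grid); an unknown with an
  empty thermal row (e.g. a sealed, flowless vessel element) is
  reported as isolated at assembly.
* **Sensitivity exclusions.** Offsets with $|\theta| \le$ 1e-6 °C are
  excluded from the averaged coefficient (the ratio diverges as
  $\theta \to 0$ and round-off dominates below that floor) and counted
  in the report. Including vessel elements in the average is the
  default, with a flag to restrict to voxels.

## On the pressure maximum principle

Vessel nodal pressures and the heat system obey discrete maximum
principles (the upwinded thermal matrix is an M-matrix; with zero
generation all temperatures lie between $T_{in}$ and $T_\infty$, and
raising the inlet temperature can lower no temperature). The *per-voxel*
compartment pressures, however, are **not** guaranteed to stay within
$[P_{out}, P_{in}]$: the mollifier distributes a terminal's flow by fixed
weights, so the continuity relation bounds only the weighted-average
tissue pressure. A voxel holding a large weight with weak drainage can
locally exceed the inlet pressure, as a two-voxel closed form shows
(with weights $w_i$ the peak compartment pressure scales like
$w_{max}/\sum w_i^2$ times the boundary drop). The effect shrinks
rapidly as the sphere of influence grows and vanishes in the
domain-scale-$\varepsilon$ regime of the reference configuration; at the
toy generator's minimal-coverage radius it is a small but nonzero
overshoot concentrated at arterial terminals. The test suite records
this honestly: the temperature bound check passes, the voxel pressure
bound check documents the violation rather than hiding it.

## Known limitations

Steady state only (the transient terms are a documented extension point);
Newtonian blood with constant viscosity; no red-blood-cell particulate
effects; no thermoregulatory feedback or vasomotion; no radiative or
evaporative boundary exchange; single ambient temperature (a conduction
slab between two different ambient baths is validated at the
primitive-coefficient level instead); structured voxel meshes only, with
no stair-step smoothing. Published sensitivity summaries for this model
class report a slight inflation of the inlet-offset coefficient above 1
when near-ambient voxels are included at finite precision; the exact
linear-system homogeneity forces 1 here, and the exclusion floor plus
offset-variable assembly keep it there.
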