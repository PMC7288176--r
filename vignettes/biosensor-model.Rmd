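---
title: "Modelling amperometric biosensors with perforated membranes"
author: "biosensim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amperometric biosensors with perforated membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model and its assumptions

The device is a layered enzyme electrode. From the electrode upward: a
*selective membrane* (region $\Omega_1$, thickness $b_1$) permeable only to
the reaction product; an *enzyme layer* ($\Omega_2$); a *perforated
membrane* — an impermeable carrier ($\Omega_4$) pierced by axisymmetric
holes — whose holes are filled with enzyme up to a height $b_3$; and an
*external diffusion layer* ($\Omega_3$) up to the well-stirred bulk at
$z=b_5$. The holes form a hexagonal lattice, so a single axisymmetric unit
cell of radius $a_1^*$ with one hole on its axis represents the device; the
hexagon is approximated by a circle of equal area, a standard and accurate
reduction when membrane thicknesses are small compared to the device
footprint.

Within the enzyme region the substrate is converted by Michaelis–Menten
kinetics under the quasi-steady-state assumption for the enzyme–substrate
complex, $v = V_{max} S/(K_m + S)$ with $V_{max} = k_2 E_0$ and
$K_m = (k_2 + k_{-1})/k_1$ (`derive_vmax_km()`). Everywhere else transport
is pure Fickian diffusion. Modelling assumptions, all standard for this
device class:

* the bulk is well stirred: $S = S_0$ and $P = 0$ at $z = b_5$ for $t>0$;
* product oxidation at the electrode is instantaneous: $P = 0$ at $z=0$;
* the carrier is impermeable ($\Omega_4$ is excluded from the domain and
  enters only as zero-flux walls);
* the selective membrane passes no substrate — the unique mass-conserving
  closure is zero substrate flux at its top face $\Gamma_1$, and $S$ is
  simply not defined in $\Omega_1$;
* no product inhibition, no reverse catalytic step, no mediator, no
  convection inside the layers.

Nondimensionalizing (lengths by $a_1^*$, concentrations by $K_m$, time by
$a_1^{*2}/D_1^*$, `nondimensionalize()`) leaves five groups: the
diffusivity ratios $D_2, D_3$, the scaled bulk concentration
$S_0$, the geometry, and the *diffusion modulus* (Damköhler number)

$$\sigma^2 = \frac{V_{max}\, a_1^{*2}}{K_m D_1^*},$$

the ratio of the enzymatic rate $V_{max}/K_m$ to the transport rate
$D_1^*/a_1^{*2}$. Large $\sigma^2$ means the response is transport
controlled; the package's reference operating point,
$\sigma^2 = 3.33\times10^4$, is deep in that regime, so the substrate is
consumed in a thin front at the top of the enzyme region.

## Geometry: hole shapes, perforation and filling levels

`geometry_spec()` holds the dimensionless cell: radii $a_2 \le a_3 \le 1$
(hole throat and mouth) and heights $0 < b_1 < b_2 \le b_3 \le b_4 < b_5$.
Two scalar levels parameterize design studies (`geometry_from_levels()`):

* **perforation level** $\alpha = 1 - a_2$: larger $\alpha$ means a
  narrower throat, i.e. a larger impermeable fraction of the membrane;
* **enzyme filling level** $\gamma = (b_3-b_2)/(b_4-b_2)$: the fraction of
  the hole height occupied by enzyme.

Seven wall profiles $a(z)$ are supported (`hole_radius_profile()`):
cylinder (radius $a_2$ throughout — the throat parameterizes all shapes
uniformly, $a_3$ is ignored), and upward/downward cones, paraboloids and
concave paraboloids. *Orientation convention*: an **upward** shape points
upward — its narrow end $a_2$ (the apex of a cone) sits at the **top** of
the membrane ($z = b_4$, the bulk side) and the mouth $a_3$ at the enzyme
side. Downward shapes are exact mirror images through the membrane
mid-plane (a tested invariant). Paraboloids are quadratic in $z$ with zero
slope at the narrow end, concave paraboloids with zero slope at the wide
end. At $\alpha = 0$ every shape degenerates to the same three-slab stack;
$\gamma \in \{0, 1\}$ collapses the in-hole interface onto the carrier
bottom/top plane — both limits are valid and reported by
`build_unit_cell()`.

The reference geometry used throughout the tests and the acceptance script
is $b_1 = 2$, $b_2 = 4$, $b_4 = 14$, $b_5 = 16$ (layer thicknesses 2, 2,
10, 2), $a_3 = 0.1$, $D_3 = 2 D_2 = 6$, $S_0 = 1$. With $a_3$ fixed at 0.1
the admissible perforation levels satisfy $\alpha \ge 0.9$; the documented
study grid is $\alpha \in \{0.92, 0.95, 0.98\}$,
$\gamma \in \{0.1, 0.5, 0.9\}$, chosen to span the admissible range while
keeping the hole wall genuinely curved ($a_2 < a_3$).

## Discretization

**Mesh.** `generate_mesh()` builds a boundary-fitted triangulation of
six-node (quadratic) triangles: structured blocks for the full-width slabs
and a mapped block inside the hole whose radial coordinate follows $a(z)$,
with all nodes — midside nodes included — on the exact wall curve
(isoparametric quadratic geometry). Region interfaces and the in-hole
enzyme interface are mesh lines, so no element crosses an interface and
tags are exact. Meshed region areas match closed-form areas from
$\int a(z)\,dz$ to near machine precision (a tested invariant), and element
Jacobians are verified positive at every quadrature point. Optional
geometric grading refines toward the electrode and toward the reaction
front at the enzyme interface. The narrow hole produces deliberately
anisotropic elements; these are aligned with the mapping and are harmless
for this diffusion-dominated problem.

**Weak form.** The axisymmetric weak form uses the volume measure
$r\,dr\,dz$: stiffness $\int D\, \nabla\xi_k\!\cdot\!\nabla\xi_i\, r$, mass
$\int \xi_k \xi_i\, r$, source $\pm\sigma^2\int \frac{S}{1+S}\xi_i\, r$ on
$\Omega_2$. This self-adjoint form is the standard equivalent of the
strong axisymmetric operator
$\Delta = \partial_{rr} + r^{-1}\partial_r + \partial_{zz}$ (an equivalent
formulation moves the $1/r$ term into a separate non-symmetric integral;
the r-weighted form is preferred because it preserves symmetry and
positive-definiteness exactly). Interface matching — continuity of
concentration and of normal flux $D\,\partial_n c$ — is enforced weakly by
using a single continuous field per species with region-wise diffusivity, which
in a conforming Galerkin setting reproduces flux continuity without
explicit constraint equations. Integration uses a seven-point (degree-5)
symmetric triangle rule, comfortably exact for the quadratic basis and
accurate for the $r$-weighted curved-element integrands.

**Fields and boundary conditions.** $P$ lives on all nodes with
$D = (1, D_2, D_3)$; $S$ only on nodes of $\Omega_2\cup\Omega_3$ with
$D = (D_2, D_3)$. Dirichlet values ($P=0$ at electrode and bulk face,
$S=S_0$ at the bulk face) are imposed by elimination, exact at nodes; all
remaining boundaries are natural (zero flux). The initial state is zero
everywhere with the bulk values imposed from the first step — the mild
startup discontinuity is discussed below.

## Time stepping and the nonlinear solve

The default scheme is backward Euler with $\Delta t = 0.01$ (dimensionless;
Crank–Nicolson is available), chosen for robustness against the stiff
source at $\sigma^2 = 3.33\times10^4$. Because the substrate equation does
not depend on the product, each step solves the nonlinear substrate block
by Newton–Raphson and then the linear product block; the convergence
criterion is the residual sum of squares over all free equations,
$\sum R_i^2 \le 10^{-7}$, recorded per step and asserted in the tests. On
the linear problem Newton converges in exactly one iteration (tested); on
stiff steps the consistent Jacobian gives the expected superlinear
contraction. Every accepted run reports its worst residual; the steady
current is insensitive to the step (halving $\Delta t$ moves $I$ by
$<10^{-3}\,\%$ at the reference point — computed in the acceptance script),
so after the early transient the step may grow geometrically
(`dt_growth`), which the bundled profiles use.

Two numerical choices deserve justification:

* **Source evaluation through undershoots.** A quadratic basis does not
  obey a discrete maximum principle, so the sharp reaction front produces
  small negative substrate excursions on coarse meshes. The rational
  Michaelis–Menten term $S/(1+S)$ is smooth for $S > -1$ and acts as a
  restoring force for $S<0$, so it is evaluated as-is rather than clamped:
  a clamp's derivative kink makes Newton chatter just above the $10^{-7}$
  criterion, while the smooth evaluation keeps the Jacobian consistent and
  convergence quadratic. Undershoot below $-0.5$ aborts the run as a mesh
  failure. The observed steady-state undershoot on the coarse profile is
  $\sim 10^{-4} S_0$.
* **Startup overshoot tolerance.** Imposing $S = S_0$ on the bulk face of
  a zero field at $t=0$ is a discontinuity; its Gibbs oscillation
  transiently overshoots $S_0$ by up to $\sim1\%$ on realistic meshes and
  decays within a few steps. The solver therefore aborts only when
  $\max S > S_0(1+\varepsilon_{over})$ with $\varepsilon_{over} = 0.05$ by
  default, and records the worst excursion (`S_range`); the tests assert
  the tight bound on the late-time field.

## Observables

The current is extracted by the **consistent boundary-flux** method: the
discrete residual of the product equation evaluated at the electrode rows
equals the weak boundary flux, which is superconvergent and exactly
mass-conserving. A direct gradient-quadrature estimator
(`electrode_current(..., "gradient")`) serves as an independent
cross-check; the two agree to a few $10^{-6}$ relative on refined meshes.
`mass_balance_report()` closes the ledger — substrate influx = total
turnover = product efflux — both consistently (closure $\sim10^{-4}$) and
via direct gradients (closure $\sim10^{-3}$, shrinking under refinement).

Steady state is a limit, so a practical rule is needed: the trace is
declared steady when the current changes by less than `eps_ss` $=10^{-4}$
(relative) over a trailing window of 1 time unit. Tightening `eps_ss`
tenfold moves $I$ by well under 0.1 % (tested on analytic traces). The
half-time $T_{1/2}$ is the first time $i(t)$ reaches $I/2$, refined by
linear interpolation between samples, with interpolation error below the
local sampling step.

## Independent oracles

Two reference solvers, sharing no code with the finite-element path, guard
correctness:

* `solve_1d_transient()`: a conservative second-order finite-difference
  multilayer solver for the fully open cell ($\alpha = 0$), with the same
  kinetics and boundary conditions, backward Euler and Newton. The 2-D
  solver at $\alpha=0$ matches it to $\sim10^{-4}$ relative on $I$ and
  $\sim2\times10^{-4}$ on $T_{1/2}$ across $\sigma^2\in\{1, 10^2,
  3.33\times10^4\}$.
* `analytic_linear_steady()`: the closed-form steady current of the
  first-order ($S \ll 1$) limit — hyperbolic cosine profile in the enzyme
  layer, linear profiles in the passive layers, flux-matched, evaluated in
  an overflow-safe `tanh` form. The formula is itself verified in the test
  suite against a brute-force fine-grid finite-difference solve of the
  linear two-point problem ($10^{-4}$ agreement), and the nonlinear
  solvers collapse onto it for $S_0 \le 10^{-3}$.

## Solver profiles and problem sizes

Two bundled profiles (`solver_profile()`) fix the mesh/stepping trade-off:
`"default"` ($h = 0.5$, 4 radial hole elements, $\Delta t_0=0.01$, ~700
nodes at the reference geometry) for quantitative single runs, and
`"fast"` ($h = 1$, 3 radial hole elements, $\Delta t_0=0.02$, ~290 nodes)
for property sweeps; a full 7-shape × 3×3 grid runs in about half a minute
with the fast profile. The two profiles agree on every ordering and
monotonicity statement and differ by $\sim0.2\%$ in $I$ at the reference
point, so sweeps are run fast and headline numbers on the default profile.

## Findings and known limitations

On the documented grid the model's response surface is unambiguous and
mesh-independent:

* the **cylindrical** hole gives the smallest steady current in every grid
  cell, the **upward concave paraboloid** the largest and also the largest
  half-time; the shape alone changes $I$ by a factor ≈ 3 at fixed
  $(\alpha,\gamma)$, and wide-bottomed shapes (which concentrate hole
  volume at the enzyme side and choke product escape at the top) are
  systematically the strongest;
* $T_{1/2}$ **increases with the filling level** $\gamma$ in every cell:
  more filling moves the reaction front away from the electrode;
* the steady current **decreases** with the perforation level $\alpha$ —
  steeply, near-exponentially as $\alpha \to 1$ — and **decreases** with
  $\gamma$ (ratio $I_{\gamma=0.9}/I_{\gamma=0.1} \approx 0.6$). Both
  directions follow from transport alone in the strong-reaction regime:
  the front sits at the enzyme top, so
  $I = S_0/(R_{\uparrow}+R_{\downarrow})$ with the two resistances taken
  through the hole; raising $\gamma$ converts hole length from the faster
  $D_3$ to the slower $D_2$ path, and raising $\alpha$ shrinks the hole,
  the dominant resistance. The measured ratio matches this closed-form
  resistance argument to two digits. Claims that the current *rises* with
  a "perforation level" refer to conventions in which that level measures
  hole openness; under the convention used here ($\alpha = 1-a_2$, larger
  $\alpha$ = more blocked) the monotonicity is necessarily reversed.
  $T_{1/2}$ is not monotone in $\alpha$ for all shapes, and the cylinder —
  while fastest among shapes for low filling — is not the fastest shape in
  every grid cell.

What the simulated conditions do not capture about real devices:
convection in the bulk (treated as perfectly stirred), electrode fouling
and noise, product inhibition or mediator kinetics, partitioning
coefficients at layer interfaces (concentrations are taken continuous),
and 3-D effects of the true hexagonal cell. Passing tests therefore
establish the correctness of the stated model, not the fidelity of any
particular laboratory device.
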