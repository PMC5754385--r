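---
title: "Inextensible Cosserat-rod simulation of endovascular instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inextensible Cosserat-rod simulation of endovascular instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endorod)
```

## The model

A catheter or guidewire is a thin elastic body whose cross-sections carry
orientation: a Cosserat rod. `endorod` discretizes the centreline into
mass points $\mathbf r_i$ and attaches to each edge a material frame, a
unit quaternion $q_j$ whose third director $\mathbf d_3(q_j)$ should
follow the edge tangent. Comparing adjacent frames gives the discrete
Darboux vector

$$\Omega_k = \frac{2}{\ell}\,\mathrm{Im}\!\left(\bar q_k \otimes q_{k+1}\right),$$

whose first two components measure bending and whose third measures
twist. The elastic energy per interior joint is
$\tfrac{\ell}{2}\left[EI\,(\Omega_1^2+\Omega_2^2) + GJ\,\Omega_3^2\right]$
(with optional intrinsic values for shaped tips), where $I=\pi r^4/4$ and
$J=2I$. Frames and points are only loosely coupled: the *parallel
constraint* penalizes the misalignment between $\mathbf d_3$ and the unit
edge vector with energy $\tfrac{K_p \ell}{2}\,\lVert \mathbf d_3 -
\hat{\mathbf e}\rVert^2$, generating restoring forces on both edge
endpoints and a torque on the frame. All generalized forces are the
analytic negative gradients of these energies; the test suite verifies
them against central finite differences to $10^{-5}$ relative.

Inextensibility is **not** a penalty. Each segment carries an equality
constraint $|\mathbf r_{i+1}-\mathbf r_i| = \ell$; the constraint Schur
complement $J M^{-1} J^\top$ along a chain is symmetric tridiagonal
(diagonal: summed endpoint inverse masses; off-diagonal:
$-w\,\hat{\mathbf d}_i\!\cdot\!\hat{\mathbf d}_{i+1}$) and is solved
exactly by the Thomas algorithm in *global* mode, or swept
constraint-by-constraint in *local Gauss–Seidel / Jacobi* modes. A
*penalty* mode (stretch springs at the largest stable stiffness, found by
a deterministic 1000-step probe with bisection) is retained as the
extensible baseline for benchmarking.

## The per-step pipeline

Each step of `simulate_insertion()`:

1. **Insertion drive.** The proximal boundary is kinematic: the first
   not-yet-inserted point moves along the insertion axis at the scheduled
   push speed and twists at the scheduled twist rate; a mass point
   activates whenever the inserted length crosses a multiple of the rest
   segment length.
2. **Explicit force integration.** Semi-implicit (symplectic) Euler for
   point velocities and frame angular velocities, with implicit viscous
   damping and quaternion renormalization each step.
3. **Collision detection.** Broad phase: sphere-vs-AABB descent of a
   bounding-volume hierarchy built once over the vessel triangles (median
   split on the longest centroid axis, leaves fattened by a margin) and
   only *refitted* bottom-up when the mesh moves, so cardiac keyframe
   motion costs one pass over the nodes. Narrow phase: exact closest
   point on each candidate triangle; triangles within one instrument
   radius contribute their lumen-oriented normals weighted by penetration
   depth, and the aggregated normal is renormalized (deepest-triangle
   fallback for perfectly opposing walls).
4. **Block-iterative Projected Gauss–Seidel.** Per outer iteration:
   distance phase, then concentric guidewire-in-catheter phase, then
   contact phase. The distance phase solves the Newton step of
   $C(\mathbf x + \Delta t\,\mathbf v) = (1-\beta)\,C(\mathbf x)$
   re-linearized at predicted positions, so $\beta = 0$ reduces to pure
   violation-rate zeroing, $\beta=1$ (the default) to full position
   projection, and the outer-iteration count governs how exactly the
   nonlinear chain is satisfied — with 25 global iterations the measured
   residual compression of the benchmark rod is 0.0000 %. Inside the
   simulation loop the solve is split: momentum-carrying impulses zero
   the violation rates, while the positional Newton correction rides the
   same pseudo-velocity channel as the contact stabilization, so even
   hard jams are projected without pumping momentum. Contacts receive
   non-negative accumulated normal impulses and Coulomb-cone-clamped
   friction ($|j_t| \le \mu j_n$); the depth-stabilization share uses
   split impulses (a pseudo-velocity that moves positions but carries no
   momentum), which eliminates Baumgarte bounce and keeps resting
   penetration well under a tenth of the instrument radius.
5. **Position update** from the corrected velocities.

The concentric phase links every dynamic guidewire point to its nearest
catheter segment; impulses act perpendicular to the catheter tangent
(coaxial sliding is free), are split between the segment endpoints with
barycentric weights $(1-w, w)$, and conserve linear momentum exactly.

## Parameters, units and the time step

Everything internal is SI; file interfaces use millimetres. Defaults:

| parameter | default | meaning |
|---|---|---|
| `dt` | 1 ms | physics step (haptic-rate regime) |
| `young_modulus_shaft` | 5e6 Pa | shaft bending modulus $E_b$ |
| `radius` | 0.4 mm | cross-section radius $r$ |
| `density` | 8e6 kg/m^3 | numerical mass scaling $d$ (see below) |
| `parallel_spring_constant` | 0.2 N | $K_p$ |
| `tip_modulus_ratio` / `tip_point_count` | 0.5 / 5 | tip softening $\alpha$ |
| `friction_coefficient` | 0.3 | wall Coulomb $\mu$ |
| `damping` | 0.5 /s | viscous mass-proportional damping |
| `stabilization` | 0.2 | Baumgarte factor $\beta$ |

Three numerical choices deserve explanation.

**Mass scaling.** With explicit integration at a 1-ms step, the
admissible stiffness of the point dynamics is bounded by
$K_p/\ell \lesssim m/\Delta t^2$. Physical densities put a thin wire far
outside that bound, so the density default is a *numerical* parameter:
it sets the stability margin and the (irrelevant, for quasi-static use)
dynamic time scale, while equilibrium shapes, contact geometry and the
compression behaviour are mass-independent. Treating density as a free,
calibratable quantity rather than a tabulated constant is intrinsic to
this model family, and `optimize_parameters()` exposes it as such.

**Frame inertia and twist stiffness.** The rotational inertia of a thin
edge is so small that frame dynamics would demand sub-microsecond steps.
Frames therefore carry a regularized inertia
$J_\mathrm{rot} = \max(\text{physical},\; s\,k_\mathrm{rot}\Delta t^2)$
(`inertia_safety` $s=4$) and are damped critically on their own
regularized time scale, so they track the elastic/parallel energy
minimum quasi-statically instead of ringing. The shear modulus is the
derived $G = t\,E_b/(2(1+\nu))$ with $\nu = 0.3$ and a `twist_stiffening`
multiplier $t=10$: instruments resist twist nearly rigidly, and the
inertia regularization is what keeps that stiffness stable at the 1-ms
step. $G$ is never calibrated.

**Newton-style distance phase.** A classical Baumgarte right-hand side
saturates at $C/(1+\beta)$ per step no matter how many iterations run;
formulating each iteration as a Newton step on the end-of-step violation
restores the expected behaviour, where the iteration count (not the
stabilization factor) controls how exactly inextensibility holds.

## Synthetic phantoms and what they do (not) represent

`make_tube_phantom()` builds straight–toroidal–straight tubes with exact
analytic centrelines; hemispherical end domes keep the mesh watertight
while leaving *every* surface vertex exactly one lumen radius from the
centreline, which the tests exploit as a construction oracle.
`make_stenosed_vessel()` narrows the lumen by a smooth cosine-squared
bump, producing topology-matched stenosed/healthy pairs for balloon
morphing.

The canonical compression benchmark — a 255-mm, 256-point rod pushed at
20 mm/s into a capped tube (2.5-mm lumen, 90° bend of 30-mm radius
between 100-mm straights, `dt` = 1 ms) — reproduces the *structure* of
the published comparison: the extensible penalty baseline compresses
visibly, one global tridiagonal solve per step is already visually
inextensible, local sweeps converge inverse-exponentially with
Gauss–Seidel dominating Jacobi, and 25 global iterations eliminate
compression to the reporting precision. The *absolute* percentages run
several-fold below the published ones: a single smooth bend in a wide
lumen simply offers far less frictional and geometric resistance than
the tortuous coronary anatomy used originally (which is not public).
Passing the structural tests therefore says nothing quantitative about
real coronary trees; it validates the solver hierarchy, not the anatomy.
Because the published table pairs millimetre and percentage values with
inconsistent denominators, the benchmark reports compression over both
documented bases (total active nominal length, and the post-bend
portion) and records which base each reported number uses.

## Calibration

`rms_error()` implements the root-mean-square of nearest Euclidean
distances from the simulated mass points inserted in the phantom to a
reference centreline polyline (segment interiors included); membership
in the phantom uses the analytic lumen test. `optimize_parameters()`
minimizes this objective over any subset of
$(E_b, r, d, K_p, \alpha)$ — never $G$ — with multi-start Nelder–Mead in
a log-transformed box: the parameters are positive and span orders of
magnitude, the objective is a deterministic black box, and multi-start
guards against contact-switching ruggedness. Each evaluation runs the
full pipeline through the insertion schedule and settles to equilibrium
(max point speed < 1e-5 m/s), bit-reproducibly.

The shipped study condition is a 60-mm, 61-point wire inserted 55 mm
into a 60°-bend tube so that the softened tip rests *inside* the bend:
there both $E_b$ (chord-versus-hug across the bend) and $\alpha$ (tip
conformity) leave distinct signatures. The calibration wire is
*lubricated* ($\mu = 0$, as for hydrophilic-coated instruments) and
settled under strong damping (5 /s): with wall friction the equilibrium
inside the tube is history-pinned and the objective becomes a rugged,
effectively non-identifiable function of the parameters, whereas the
frictionless equilibrium depends smoothly on them. Under these
conditions, recovering $(E_b, \alpha)$ from a self-generated reference
succeeds to a few tenths of a percent. The published sub-2-mm phantom accuracy against CT-scanned
real instruments is *not* reproducible here — it requires that scanned
dataset — so the synthetic recovery experiment stands in, and measures
identifiability of the model rather than realism of the anatomy.

## Procedure models

Contrast is an ordered sphere chain with conservative upwind advection
(fill moves down-chain at the per-sphere flow speed times a heartbeat
factor $1 + A\sin 2\pi\phi$, $A = 0.5$); injection enters sphere 0,
outflow leaves the last sphere, and the budget closes to 1e-12 per step.
Opacity is fill scaled inversely with sphere volume, clamped to [0, 1];
an optional washout decay (default 0) is exposed. Balloon spheres ride
the distal guidewire, inflate linearly over 2 s toward their target
radius but are clipped every step by the exact distance to the morphed
vessel surface; the stenosed-to-healthy vertex morph ratchets with the
maximum inflation reached, making the dilation persistent through
deflation. The stent copies the balloon until release (rejected below
50 % inflation), then anchors each sphere to its nearest vessel vertices
with critically damped vector springs (settling time 0.5 s), so it
holds position and follows wall motion rigidly. Cardiac motion is a
cyclic 24-keyframe vertex interpolation, bit-exact at the knots, feeding
the AABB refit.

## Numerical edge cases and limitations

* Zero-length segments raise a degeneracy error rather than producing
  NaNs; non-finite state aborts with the offending quantity named.
* Contact ties are broken by ascending point index; all code paths are
  deterministic given inputs, so identical configurations reproduce
  bit-identically (the tests assert this).
* Energy monotonicity under damping holds in the resolved-timestep
  regime ($\omega\Delta t \ll 1$); near the stability edge the
  symplectic-Euler shadow energy fluctuates within a bounded band, which
  is expected and harmless for the quasi-static questions the simulator
  answers.
* Self-collision of a rod, rod–rod contact outside the concentric
  coupling, swept (continuous) collision detection, haptic force
  rendering and real-time guarantees are out of scope.
* Friction inside the catheter lumen is not modelled (wall friction
  only); concentric links are rebuilt every step for guidewire points
  proximal of the catheter tip.

## Problem sizes used by the shipped experiments

The benchmark harness runs eleven solver variants of the full 256-point,
12.75-s insertion; the calibration recovery uses the 61-point scenario
above (about 40 objective evaluations); collision oracles audit 50
random poses against brute force. These sizes were chosen so the whole
validation story — unit oracles, benchmark, recovery — runs in a few
minutes on a single core while still exercising the canonical 256-point
discretization.
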