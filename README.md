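# endorod

`endorod` is a headless physics engine for simulating the instruments of
endovascular intervention — guidewires and catheters — inside vessel
geometry, written for people building surgical-training simulators,
studying instrument mechanics, or benchmarking constraint solvers for
thin inextensible rods. There is no GUI and no haptics: the package is
the physics core, a calibration toolkit, synthetic vascular phantoms,
and a benchmark harness, all scriptable from R or a small CLI.

## The model

An instrument is a **discrete Cosserat rod**: mass points `r_i` along
the centreline, and a unit-quaternion **material frame** `q_j` on every
edge. Adjacent frames define the discrete Darboux vector
`Ω_k = (2/ℓ) Im(q̄_k ⊗ q_{k+1})`, penalized by bending (`E I`) and
twisting (`G J`) stiffness, with the distal tip softened by a ratio
`α` over a configurable number of end points. The CoRdE-style
**parallel constraint** couples each frame's third director to its edge
tangent through a `K_p`-weighted penalty, with forces and torques that
are exact analytic gradients of the energy.

Inextensibility is enforced by a chain of equality **distance
constraints**, one per segment. Their Schur complement along the chain
is a symmetric tridiagonal system, solved each iteration of a
block-iterative **Projected Gauss–Seidel** pipeline:

1. distance phase — exact global tridiagonal (Thomas) solve, or local
   Gauss–Seidel / Jacobi sweeps, or a stretch-penalty baseline;
2. concentric phase — impulses keeping guidewire points on the catheter
   axis while leaving coaxial sliding free;
3. contact phase — fat-AABB BVH broad phase, sphere-vs-triangle narrow
   phase with depth-weighted normal aggregation, non-negative normal
   impulses and Coulomb friction (`|j_t| ≤ μ j_n`), with split-impulse
   position stabilization.

Calibration minimizes the RMS nearest distance between simulated mass
points and a reference centreline,
`f(E_b, r, d, K_p, α) = sqrt(1/N Σ minDist(p_i)²)`,
by multi-start Nelder–Mead in log space (the shear modulus stays fixed).
Angioplasty support models — contrast advection through a sphere chain,
balloon inflation with stenosed→healthy mesh morphing, stent release on
anchored springs, 24-frame cardiac keyframe motion — complete the
procedure toolkit.

See `vignettes/rod-simulation-methods.Rmd` for the full account of the
discretization, the solver, parameter defaults and their rationale, and
known limitations.

## Worked example

Push a 255-mm, 256-point guidewire at 20 mm/s into a watertight bent
tube (2.5-mm lumen, 90° bend) and measure compression with a single
global distance solve per step:

```r
library(endorod)

scenario <- canonical_compression_scenario()
rod <- build_rod(scenario$n_points, scenario$total_length, scenario$params,
                 base_position = scenario$phantom$centreline$points[1, ],
                 inserted_length = 0)
rod <- advance_insertion(rod, dt = 0)
sim <- simulate_insertion(rod, scenario$params, scenario$phantom,
                          scenario$drive, sim_config(),
                          duration = scenario$duration)
sim
#> Rod simulation: 12750 steps (0 settling), compression 0.333%, max segment error 0.0977 mm
```

The rod stays within a tenth of a percent of its nominal length even
though the tube centreline (247 mm) is shorter than the rod — the
excess feed is absorbed by buckling within the lumen. The full solver
comparison:

```r
report <- run_compression_experiment(seed = 1)
report
#> Rod compression benchmark
#>   256-point rod, 255 mm, push 20 mm/s, dt 1 ms
#>   penalty stiffness (largest stable): 2.33e+03 N/m
#>                mode iterations compression_percent compression_percent_postbend compression_mm  status
#>             penalty          1                0.42                         0.06           1.08      ok
#>  global_tridiagonal          1                0.33                         0.37           0.85      ok
#>  global_tridiagonal          5                0.00                         0.00           0.01      ok
#>  global_tridiagonal         10                0.00                         0.00           0.00      ok
#>  global_tridiagonal         25                0.00                         0.00           0.00      ok
#>  local_gauss_seidel          1                0.37                         0.06           0.94      ok
#>  local_gauss_seidel         10                0.02                         0.01           0.05      ok
#>  local_gauss_seidel        100                0.00                         0.00           0.00      ok
#>        local_jacobi          1                  NA                           NA             NA blow-up: numerical blow-up: non-finite velocity at point 70
#>        local_jacobi         10                0.07                         0.02           0.17      ok
#>        local_jacobi        100                0.00                         0.00           0.01      ok
```

Reading the table: the extensible stretch-penalty baseline loses a full
millimetre; one exact global solve per step is already visually
inextensible; local sweeps converge inverse-exponentially with
Gauss–Seidel dominating Jacobi; and 25 global iterations eliminate
compression to reporting precision. (A single Jacobi sweep is
marginally convergent and diverges under the end-of-tube jam; the
harness records the blow-up and continues.)

Calibrating `(E_b, α)` against a self-generated reference centreline in
a 60°-bend phantom:

```r
res <- optimize_parameters(problem, n_starts = 3, maxit = 40, seed = 1)
res
#> Instrument calibration result
#>   RMS centreline distance: 0.0002 mm (43 evaluations)
#>   young_modulus_shaft = 5.015e+06
#>   tip_modulus_ratio = 0.4983
```

recovering both parameters to a few tenths of a percent (truth:
`5e6`, `0.5`).

## Command line

A thin Rscript front end lives at `inst/cli/endorod`:

```sh
Rscript inst/cli/endorod compress-bench --out report_dir --seed 1
Rscript inst/cli/endorod make-phantom --out tube --radius-mm 2.5 --bend-deg 90
Rscript inst/cli/endorod simulate --config inst/extdata/example_scenario.yaml --out traj
Rscript inst/cli/endorod calibrate --phantom tube.obj --reference line.csv --free Eb,alpha
Rscript inst/cli/endorod angioplasty --out procedure
```

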