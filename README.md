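# avm: active vertex model simulation of confluent epithelial tissues

Confluent epithelia — sheets of cells with no gaps or overlaps — behave
mechanically like dense soft matter: below a critical cell shape they are
solid-like and cells never swap neighbours; above it, or under enough
active driving, the tissue fluidises through T1 intercalation events.
`avm` is an R package for cell-resolution simulation of this physics, for
researchers in tissue biomechanics, developmental biology and active
matter.

The model tracks **cell centres** as particles.  The tissue shape is the
Voronoi tessellation dual to the Delaunay triangulation of the centres,
and the forces on the centres derive from the vertex-model energy on that
tessellation,

    E = Σ_i K_i/2 (A_i − A_i⁰)² + Σ_i Γ_i/2 P_i² + Σ_i Σ_{e∈∂Ω_i} Λ_e l_e
        + soft core,

with per-cell-type area moduli `K`, perimeter moduli `Γ` and a junction
tension matrix `Λ` over type pairs (including the boundary type `M`).
Cell dynamics is overdamped Langevin motion with self-propulsion `f_a`
along a fluctuating polarity (Euler–Maruyama integration), with optional
polar, velocity and shape alignment of the polarity.  The Delaunay
property is maintained by equiangulation edge flips, which *are* the T1
neighbour exchanges — junctions shrink continuously to a point and regrow
between the other cell pair, no mesh surgery needed.  The package also
implements cell growth/division/death, a flexible ghost-particle boundary
line with line tension and bending stiffness (fixed or free, with
fixed loop topology), scenario generators (disk, annulus, rectangular
strips, confined cavity; two-type tissues for sorting), and trajectory
observables: self-intermediate scattering function and α-relaxation time,
T1 statistics, per-cell virial/Hardy stress and pressure, neighbour
distributions, demixing index and solid/liquid/unstable phase
classification.

The key dimensionless knob is the shape factor `p0 = P0/√A0`
(`P0 = −Λ/Γ`, `A0 = π`): regular hexagons, pentagons, squares and
triangles have `p0` = 3.722, 3.812, 4.000, 4.559, and the pentagon value
marks the solid–liquid transition.

## Worked example

A 100-cell disk with a fixed boundary, deep in the solid regime
(`p0 = 3.39`, weak drive `f_a = 0.01`, polarity persistence time 100):

```r
library(avm)
tis  <- initPacking("disk", N = 100, seed = 1)
mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.39),
                   kCore = 1, aCore = 1)
act  <- ActiveParams(fa = 0.01, Dr = taurInverse(0.01), dt = 0.01)
tis  <- relaxTissue(tis, mech, nSteps = 200, dt = 0.01)
traj <- runSimulation(tis, mech, act, nSteps = 5000, snapshotEvery = 100,
                      seed = 2)
pm <- classifyPhase(traj, after = 10)
pm$classification      # "solid"
pm$t1Rate              # 0       — no neighbour exchanges in 50 time units
pm$tauAlpha            # Inf     — F(q, t) never decays below 1/2

cells <- dualCells(traj@finalTissue)
mean(cells$area)                            # 2.949  (cells compressed below A0 = pi
                                            #         by the fixed boundary)
mean(cells$perimeter / sqrt(cells$area))    # 3.811  (observed shape factor)

st <- hardyStress(traj@finalTissue, mech)
sum(st$pressure * st$area) / sum(st$area)   # -0.202 (net tension: the tissue
                                            #         pulls inward on the rim)
```

Raising `fa` or `p0` fluidises the tissue: `sweepPhase()` scans a
`p0 × fa` grid and tabulates `tauAlpha`, T1 rates and the classification
per state point.  `sortingExperiment()` runs two-type tissues with
differential junction tension and returns the demixing-index time series.
A thin command-line front end (`inst/scripts/avm`) exposes
`init` / `run` / `sweep` / `analyze` over YAML configs for shell use.

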