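---
title: "Simulating confluent epithelia with an active vertex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating confluent epithelia with an active vertex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avm)
```

## The model

A confluent epithelial monolayer is represented as a set of particles in
the plane.  Interior particles are cell centres; each owns the Voronoi cell
of the Delaunay triangulation built over all particles, so the tissue is a
gap-free polygonal tiling at all times.  Ghost particles strung along one
or more closed loops mark the tissue edge: they bound the Voronoi cells of
the outermost cells but own no cell themselves.

The mechanics is the vertex-model energy evaluated on this dual tiling,

$$E = \sum_i \frac{K_i}{2}\,(A_i - A_i^0)^2
    + \sum_i \frac{\Gamma_i}{2}\,P_i^2
    + \sum_i \sum_{e \in \partial\Omega_i} \Lambda_e\, l_e
    + \sum_{\langle ij\rangle} \frac{k}{2}\,(a - r_{ij})^2\,
      \Theta(a - r_{ij}),$$

with $A_i$, $P_i$ the area and perimeter of cell $i$, $A_i^0$ its native
(target) area, $K_i$ and $\Gamma_i$ the area and perimeter moduli, and
$\Lambda_e$ the tension of junction $e$, looked up from a symmetric matrix
over the cell types of the two particles whose Delaunay edge the junction
bisects (the ghost type is written `M`, so cell--boundary contacts carry
their own tensions).  The junction sum runs over each cell's own edges:
an interior junction is paid by both adjacent cells, a cell--boundary
junction once.  With uniform tension this is exactly the
preferred-perimeter form $\sum_i \Gamma/2\,(P_i - P_0)^2$ with
$P_0 = -\Lambda/\Gamma$, up to the constant $N\Lambda^2/(2\Gamma)$ per
tissue — an identity the test suite asserts.  The last term is a harmonic
soft core of range $a$ (the unit of length) between Delaunay-adjacent
particle centres; it has no counterpart in the polygon energy and exists
to keep centres from collapsing onto each other in the floppy regime.

The force on every particle — cell centres and ghosts alike — is the exact
negative gradient of $E$ with respect to that particle's position.  Because
the energy is naturally a function of the Voronoi vertices (triangle
circumcenters), the gradient is assembled by the chain rule: per-cell
gradients with respect to each vertex, then the analytic $2\times2$
Jacobian of the circumcenter with respect to each of its three sites.  The
result is local (only particles sharing a triangle with one of a cell's
vertices contribute) but not pairwise.  The master correctness check,
applied term by term, is agreement with a central finite-difference
gradient of the scalar energy to a relative $10^{-5}$.

Dimensionless control parameter: the shape factor
$p_0 = P_0/\sqrt{A_0}$.  The package fixes $K = 1$, $A_0 = \pi$ and the
soft-core range $a = 1$, so time is measured in units of $\gamma/(K a^2)$,
and `lambdaForP0()` maps a target $p_0$ to the junction tension.  Regular
hexagons, pentagons, squares and triangles correspond to $p_0 = 3.722$,
$3.812$, $4.0$ and $4.559$; the pentagon value is the solid--liquid
transition point of the model.

## Delaunay maintenance and T1 transitions

As cell centres move the triangulation is kept Delaunay by equiangulation:
any interior edge whose opposite angles sum to more than $180^\circ$ is
flipped, from a FIFO queue that re-enqueues the four quadrilateral edges
after each flip.  Cocircular ties (incircle determinant within
$10^{-12}$, scaled) are *not* flipped, which avoids flip oscillation.
Each flip replaces exactly one Voronoi junction: the junction between two
cells shrinks continuously to a point, the flip occurs, and a new junction
between the other two cells of the quadrilateral grows.  This *is* the T1
neighbour exchange; flips whose four particles are all interior cells are
logged as T1 events.  Flips that would invert a triangle, or whose
replacement diagonal already exists (possible transiently when particles
move far in one step), are deferred until a neighbouring flip changes the
local configuration.

From-scratch construction (initialisation, division, death, boundary
edits) uses incremental Bowyer--Watson insertion.  Exactly cocircular
inputs — regular ghost rings, lattices — make the textbook cavity test
inconsistent, so insertion runs on coordinates with a deterministic
symbolic-perturbation jitter of relative size $10^{-8}$ and the result is
equiangulated with the exact coordinates, which restores exact
Delaunayhood (ties may resolve either way; both resolutions are valid).
The test suite checks the resulting edge sets against an independent
from-scratch construction (`scipy.spatial.Delaunay`) on a thousand random
instances, accepting tie-degenerate differences only when both
triangulations pass the strict empty-circumcircle certificate.

## Dynamics

Cell centres obey overdamped Langevin dynamics,
$$\gamma \dot r_i = f_a\, n_i + F_i + \nu_i(t), \qquad
  \gamma_r \dot\theta_i = \tau_i + \nu^r_i(t),$$
integrated with the Euler--Maruyama scheme: the polarity
$n_i = (\cos\theta_i, \sin\theta_i)$ sets the direction of the active
self-propulsion $f_a$ (free-cell speed $v_0 = f_a/\gamma$), $\nu$ and
$\nu^r$ are white noises of strength $2D$ and $2D_r$.  The polarity
persistence time quoted in parameter tables is
$\tau_r = \gamma_r/(2 D_r)$; `taurInverse()` converts a quoted
$\tau_r^{-1}$ into $D_r$, while the dynamical decay time of
$\langle n(t)\cdot n(0)\rangle$ is $1/D_r$ at $\gamma_r = 1$ (a factor-two
convention difference that the documentation keeps explicit).  Ghost
particles carry no polarity, activity or noise: in `free` mode they move
under the tissue and boundary-line forces only, in `fixed` mode (and for
`wall` ghosts always) they are immobile.

Three alignment torques can act on $\theta_i$, singly or additively:
neighbour (Vicsek-like) coupling $J_p \sum_j \sin(\theta_j - \theta_i)$;
velocity alignment $J_v \sin(\theta_v - \theta_i)$ towards the direction
of the previous step's displacement (the normalised form is used so that
$J_v$ is comparable across speeds; a cell at rest feels no torque); and
shape alignment $J_s \sin(\theta_p - \theta_i)$ towards the principal axis
of the cell shape tensor, the mean outer product of consecutive-vertex
differences.  The shape axis is defined up to sign; the sign with
$n \cdot p \ge 0$ is chosen each step, making the coupling nematic and
avoiding spurious half-turn torques.

A per-step displacement larger than $a/2$ aborts the run as a step-size
instability rather than silently corrupting the tessellation.

## Population dynamics

Native areas grow by compounding, $A^0(t+\delta t) = (1+\eta\,\delta
t)A^0(t)$, and ages advance every step.  Every `checkEvery` steps (default
25) each cell with actual area $A > A_c$ divides with probability
$\min(\chi (A - A_c)\, T, 1)$ over the elapsed interval $T$, which makes
the division law independent of the time step.  Daughters are placed at
$r \pm (\mathrm{offset}/2)\,n$ along the mother's polarity, with age zero;
each daughter inherits half the mother's native area (the mother's target
area is conserved through division — the underlying model leaves this
choice open) and the default offset is $0.5a$, small enough that daughters
stay adjacent.  A cell whose age exceeds `maxAge` is removed
instantaneously (disabled by default; the growth experiments have no
apoptosis).  After division or death the triangulation is rebuilt from
scratch; several divisions accepted in the same sweep share one rebuild,
which is equivalent to rebuilding after each since the rebuild is a pure
function of the final positions.  Stress-dependent death is deliberately
not implemented.

## The boundary line

The ghost loops carry a line tension
$\frac12\sum_{\mathrm{edges}}\lambda\,(l - l_0)^2$ and a bending energy
$\frac12\sum_i \zeta\,(\theta_i - \pi)^2$, with $\theta_i$ the angle at
ghost $i$ between its two neighbours.  Each ghost has exactly two boundary
neighbours and the loop topology (number of loops) is fixed for the whole
run: a tissue cannot split or open a hole, and `topologyGuard()` aborts a
run whose boundary became self-intersecting or mis-linked.  Edges longer
than $l_{\max} = 2 l_0$ are split at their midpoint; edges shorter than
$l_{\min} = 0.5\, l_0$ are contracted to their midpoint unless the loop
would drop below three ghosts or the merged line would self-intersect.
These thresholds keep the line resolution commensurate with the cell size
$a$; ghosts receive no stochastic force, so the boundary does not diffuse
independently of the tissue it bounds.

## Observables

* **Self-intermediate scattering function** $F(q,t) = \langle \exp(i q
  \cdot \Delta r)\rangle$ at $q = 2\pi/a$, averaged over interior cells,
  ten time origins and eight equally spaced $q$ directions (the isotropic
  average; the reference work does not state its averaging protocol).
  The $\alpha$-relaxation time $\tau_\alpha$ is the interpolated first
  crossing of $1/2$, infinite for a frozen run; tables report the sentinel
  $10\times$ run length with an explicit censoring flag.
* **T1 statistics**: counts and rates of logged flips, ghost-involved
  flips excluded.
* **Per-cell virial (Hardy) stress** assembled from the scalar tensions of
  the junction edges and the Delaunay edges — the two length sets that
  determine the energy, coupled by the kite identity $A_i = \frac14 \sum_j
  r_{ij} l_{ij}$.  Edges shared by two cells contribute half to each;
  edges involving a ghost contribute fully to their single cell.  With
  this weighting the area-weighted mean of $\mathrm{tr}\,\sigma$ equals
  the affine-dilation derivative $dE/d\ln A_{\mathrm{tot}}$ per total area
  exactly, which the tests verify against finite differences.  Pressure is
  $p = -\frac12 \mathrm{tr}\,\sigma$, so compression is positive — the
  sign convention is stated here because it is easy to get wrong.
* **Neighbour-number distributions** (interior neighbours only),
  **demixing index** (fraction of cell--cell junction length joining
  same-type cells) and **boundary-instability time** $\tau_{inst}$, the
  first time the boundary length exceeds $1.05\times$ its initial value.
* **Phase classification**: *solid* if no T1 events occurred and
  $\tau_\alpha$ exceeds the run length; *unstable* if $\tau_{inst}$ is
  finite; otherwise *liquid*.

## Scenario generation

`initPacking()` places slightly polydisperse soft disks (10% radius
spread, radii rescaled so the region area is $N\langle A\rangle/\phi$ at
packing fraction $\phi = 1$) in a disk, annulus, set of rectangular strips
or circular cavity, and relaxes them with a FIRE minimiser until the
largest net force is below $10^{-6}$ — evenly spaced cells that are not on
a grid, with mean Voronoi area within a few percent of $A_0 = \pi$.
Ghosts are laid on the rim at spacing $\approx a$, one cell-scale arc per
ghost; a cavity uses immobile `wall` ghosts and admits $\phi < 1$ so a
patch can grow into the free space.

## Worked example: a short solid-phase run

```{r example, eval = FALSE}
tis <- initPacking("disk", N = 100, seed = 1)
mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.39),
                   kCore = 1, aCore = 1)
act <- ActiveParams(fa = 0.03, Dr = taurInverse(0.1), dt = 0.01)
tis <- relaxTissue(tis, mech, nSteps = 200, dt = 0.01)
traj <- runSimulation(tis, mech, act, nSteps = 5000, snapshotEvery = 100,
                      seed = 2)
classifyPhase(traj, after = 10)
```

## Numerical choices and scaled-down study sizes

All stochastic experiments in the test suite are scaled-down versions of
the full-size protocols, with sizes chosen once as the package's study
conditions:

* *Fluidisation onset*: $N = 100$ fixed-boundary disk, $\Gamma = 1$,
  $\tau_r^{-1} = 0.01$, $f_a = 0.01$, $p_0$ swept from 3.60 to 4.00 in
  steps of 0.05; 20,000 steps at $\delta t = 0.025$ (500 time units) per
  state point, T1 rates measured after a 20% transient.  The lowest $p_0$
  with a nonzero T1 rate estimates the solid--liquid onset, expected at
  the pentagon value $p_0 \approx 3.81$.
* *Open vs fixed boundaries*: $N = 60$, $p_0 = 3.75$, $f_a = 0.05$,
  identical parameters except ghost mobility; the open system relaxes
  faster (smaller $\tau_\alpha$).  The full-size $N = 1000$ comparison
  (transition ceiling $f_a \approx 0.03$ for open systems) needs
  hour-scale runs and is provided as
  `scripts/overnight_phase_diagram.R` rather than asserted in tests.
* *Growth*: 37 cells at $p_0 = 3.10$ ($\Gamma = 1$, $\Lambda = -5.5$),
  $f_a = 0$, $\delta t = 0.005$, 24,000 steps.  The growth rate
  $\eta = 0.02$ and division constant $\chi = 0.1$ are this package's
  choices — the reference values are not published, so absolute cell
  counts are not reproducible and growth is asserted qualitatively:
  log-linear cell counts over the first three doublings
  ($R^2 > 0.98$; a small $\chi$ keeps divisions rate-limited and
  desynchronised, which is also the regime in which the exponential law
  is clean), centre-peaked radial pressure, neighbour-number mode six.
  The boundary for growth runs uses $\lambda = 0.2$, $\zeta = 0.3$: the
  bending term suppresses short-wavelength folding of the ghost line
  under outward growth, which is the failure mode of a floppier line.
* *Sorting*: 100 cells, half `r` half `b`, $f_a = 0$, positional noise
  $D = 0.02$ (the reference describes "small random fluctuations" without
  a value), tensions $\Lambda_{rr} = -6.8$, $\Lambda_{bb} = -6.2$ and
  $\Lambda_{rb} = -6.4$ (sorting) or $-6.7$ (checkerboard); the demixing
  index rises in the first case and falls below its initial value in the
  second within 100 time units.

What the synthetic scenarios do *not* emulate: real epithelia have
cell-cell friction, curved junctions, signalling-coupled mechanics and
three-dimensional structure.  Passing tests demonstrate that the
implementation solves *this* model correctly at the stated sizes, not that
the model captures any particular tissue.

## Known limitations

* No periodic domains; the geometry is always bounded by ghost loops.
* Boundary splitting/merging (holes, detachment) is not representable;
  runs that reach such configurations abort at the topology guard.
* Very large shape factors ($p_0 \gtrsim 4.6$) produce rosette-like,
  numerically delicate configurations; the soft core keeps them stable
  but their biological interpretation is doubtful.
* The Bowyer--Watson construction is $O(N^2)$; rebuild-heavy runs
  (frequent division) dominate at tens of thousands of cells.
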