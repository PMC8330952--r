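---
title: "Models and methods: stochastic reaction-diffusion simulation of chemoattractant signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rdmecell` simulates the signaling network that lets chemotactic amoeboid
cells (the social amoeba *Dictyostelium discoideum* is the reference system)
sense extracellular cAMP, adapt to uniform levels of it, and convert shallow
gradients and random fluctuations into all-or-nothing excitable activity.
This vignette describes the machinery, the three biochemical modules, the
calibration choices the package makes where published information ends, and
what the desk-scale test conditions do and do not show.

## 1. The reaction-diffusion master equation and its sampler

Space is discretized into the dual (nodal) volumes of an unstructured
tetrahedral mesh; molecules are integer counts per voxel, reactions fire
within a voxel, and diffusion is a Markov jump of a single molecule between
mesh-connected voxels. This reaction-diffusion master equation (RDME) makes
molecular noise intrinsic: there is no added noise term anywhere, the
fluctuations come from the discreteness of the events themselves, and no
state can ever go negative.

The sampler is the Next Sub-volume Method: one next-event time per voxel in
an indexed binary min-heap; when a voxel fires, Gillespie's direct method
picks the channel among its reaction propensities and the per-species
outbound diffusion rates; only the affected voxels' propensity sums are
recomputed, and unaffected voxels keep their event times rescaled by the
old/new propensity ratio. The event loop is compiled (C++), uses one named
xoshiro256++ stream per simulation, and is exact in distribution for the
RDME; the unit suite cross-validates it against an independently written
direct-method sampler on flattened small models.

Diffusion jump rates follow the finite-element convention: with the linear
(P1) stiffness matrix `K` and barycentric dual volumes `V`, a molecule with
diffusion constant `D` hops `i -> j` at rate `D * max(0, -K_ij) / V_i`.
Positive off-diagonal entries (obtuse tetrahedra) are clamped to zero and
counted. This construction satisfies detailed balance with respect to the
nodal volumes, so a diffusing tracer's stationary distribution is
proportional to them (tested by chi-square), and its mean-square
displacement grows diffusively.

Stimulus fields are piecewise constant in time; ligand-dependent
propensities are refreshed exactly at the changepoints, which keeps the
sampler exact under any step, staircase, pulse or gradient protocol.

## 2. Geometry

The cell is a hemisphere of radius 5 um resting on the substrate plane, and
only a 200-nm shell under its boundary (plasma membrane plus cytoskeletal
cortex) is meshed; the deep cytosol acts as an implicit reservoir. The
mesher triangulates the boundary (curved dome plus basal disk) with
latitude/radius rings of jittered phase at an edge length near `h_max`
(default 0.3 um), extrudes one element layer inward, and splits each prism
into three conforming tetrahedra. At the defaults this gives about 5,400
nodes and 16,100 tetrahedra with mean dual volume 8.3e-3 um^3 and a
leptokurtic volume distribution, matching the scale of the reference
discretization. Nodes within 20 nm of the boundary are membrane nodes, the
rest cortex; basal/apical is decided by height above the substrate plane.

Two mesher limitations are worth knowing. First, edge lengths slightly
exceed `h_max` along prism diagonals. Second, the membrane and cortex node
layers have equal mean volumes (within 3%) but mildly different
distribution shapes (rank-sum AUC 0.41), because the two layers are
structured extrusions rather than interior points of an unstructured
tetrahedralization; tests therefore assert location agreement, not
distributional identity.

## 3. The receptor module

Receptors bind cAMP in three affinity states (high H, low L, slow S) with
phosphorylated (desensitized) forms of H and L, giving 10 species and 26
reactions per membrane node; a fitted 2-state variant (R, R:C) is available
for cheap runs. cAMP is an external buffered field (the ligand reservoir of
a micropipette or bath is effectively infinite, so the +-1 ligand
stoichiometry is not applied), and inorganic phosphate is buffered at a
fixed concentration folded into pseudo-first-order phosphorylation rates.
The phosphate default (5.07 uM) is the package's one receptor-side
calibration constant: it was fixed once so that the pooled phosphorylated
states reach half of their saturating-step plateau at about 198 s, and then
frozen.

Because every receptor channel is (pseudo-)first order, dose-response and
equilibration questions reduce to a single-receptor Markov chain; the
package solves its stationary vector directly rather than integrating ODEs,
and inverts the dose -> occupancy map by bisection ("saturating dose" means
99% steady-state occupancy). The slow state S has no zero-ligand
interconversion path in the printed reaction set, so it holds whatever the
initial condition gives it; the zero-ligand equilibrium leaves it empty.

Two receptor timescales matter downstream: occupied receptors redistribute
between the H:C and L:C classes with a half-time of ~8 s, and the
phosphorylation pool equilibrates with a half-time of ~198 s. The *sum* of
the unphosphorylated occupied states moves only on the millisecond binding
timescale or the phosphorylation timescale, which is why the package
measures the fast receptor kinetics on the occupied-class composition (the
H:C share), not on the sum. With buffered phosphate the full zero-ligand
equilibrium is ~77% phosphorylated; protocols that need "fresh" receptors
(step half-times, pulse experiments) start from the unphosphorylated H/L
equilibrium instead, since phosphorylated-occupied receptors unbind very
slowly (minutes) and would otherwise hold the downstream pathway active
long after a pulse.

## 4. G-protein dynamics and LEGI adaptation

The heterotrimeric G-protein dissociates basally and under occupied-receptor
catalysis, and reassociates bimolecularly; totals default to 3x the
receptor count (the tabulated per-ratio rate sets from 0.1x to 5x are
included). The normalized dissociation curve is independent of the total -
the spare-receptor property - with half-maximal response near 22% receptor
occupancy.

Adaptation follows the local excitation-global inhibition (LEGI) scheme:
the fast membrane-bound excitor is dissociated G_bg, the slow inhibitor
I/I* diffuses fast (D = 20 um^2/s against 0.2 for the G-proteins) and is
activated by the same occupied-receptor signal. The printed inhibitor rate
constants are proportional to the G-protein ones to better than 1%, which
the package reads as the design it is: with activation and deactivation
both firing at the membrane, the I* steady state is exactly
`lambda * [G_bg]` at every uniform dose, with
`lambda = (kI/kE) (k-E/k-I) = 0.988`. Choosing the inhibitor total as
`lambda * G_total * (V_all / V_membrane)` makes the proportionality exact
in concentration, and this single choice is what gives the difference
scheme perfect mean adaptation. Because the basal exchange rates are of
order 1e-7/s, basal G_bg and I* levels are seeded directly at
initialization; they could never establish themselves during a simulated
run.

The response regulator RR is realized five ways:

* implicit difference (the default): per-voxel algebraic readout
  `RR = max(0, alpha0 + alpha1 (g - beta i))`, `beta = 1/lambda`;
* implicit ratio: `RR = rho (a + g)/(b + i)` with `a`, `b` set to 20% of
  the basal levels and `b = lambda a`, which makes the ratio form adapt
  exactly as well;
* explicit difference and ratio: reaction sets whose quasi-steady states
  are exactly the two readouts (the difference form needs a saturated,
  inhibitor-set zero-order RR sink, implemented as an enzyme-like gated
  channel, plus a first-order leak);
* antithetic integral feedback (AIF): an X/Y annihilation pair inside a
  feedback loop - X is produced from G_bg and activates RR, Y is produced
  jointly by I* and RR and annihilates X - so the annihilation enforces
  `kX <g> = kY2 <i RR>` and the setpoint `RR = (kX/kY2) g/i` returns to
  the common basal at every uniform dose. The printed AIF stoichiometry
  pairs the intermediates the other way around and is an open-loop leaky
  integrator whose output scales with the square root of the input; the
  package implements the closed loop its own figure narrative describes,
  and derives `kY2 = kX/(lambda alpha0)` at build time.

Common constants: basal RR `alpha0 = 2 uM` and gain `alpha1 = 25` (both
calibration constants fixed together with the excitable network, see
below). The absolute RR unit is a free choice - only the product of RR with
the excitable network's activation gain matters - and it is fixed so that a
node holds tens of RR molecules at basal, the copy-number scale at which
the molecular schemes operate away from the zero-count boundary (and the
scale of the plotted reference amplitudes); the network's RR gain `a3`
absorbs the reciprocal factor.

All three scheme families share the same basal RR and adapt perfectly in
the mean field at every uniform dose. At stochastic resolution a subtlety
appears that is worth understanding: the basal excitor/inhibitor levels are
only ~10-100 molecules per cell, so per-node signal fluctuations exceed the
basal readout, and the zero-clamp (or, for molecular RR species, the
zero-count boundary) rectifies those fluctuations into a positive shift of
the nodal-mean RR. The shift tracks the fluctuation size - it is the
dose-dependent variance leaking into the mean - so the stochastic
steady-state RR sits above the deterministic basal at populated doses while
remaining dose-insensitive across them (e.g. within ~5% between 50% and
100% occupancy). The scheme-discriminating variance behavior (difference
variance growing with dose, ratio flat to falling, AIF smallest) is the
package's reproduction of the scheme-discrimination argument.

## 5. The excitable network

Five species: RasGDP/RasGTP (the activator axis), PIP2 (fast mutual
inhibition with RasGTP: PIP2 gates Ras activation through the rational
propensity `(a30 + a3 [RR]) / (a4^2 [PIP2]([PIP2]-1) u(V)^2 + 1)` and
RasGTP drives PIP2 hydrolysis), and activated PKB substrates (PKB*s, the
slow negative feedback, drawing on a finite unmodelled pool per membrane
node). G_a2 couples stimulation to PIP2 hydrolysis through PLC.

The published parameter table for this module is not internally consistent
at its own printed copy numbers (several rate-constant magnitudes would
destroy PIP2 within milliseconds of a single RasGTP molecule, or cannot
sustain any PKB*s at rest), so the package treats the printed mantissas as
structure and fixes the magnitudes by calibration against the published
phenotype, once, with the following frozen result:

| constant | value | role |
|---|---|---|
| a1 = 0.73/s, a3 = 50/(uM s), b1 = 48.1 uM/s, b2 = 0.481/s, b3 = 19.2/(uM s), b4 = 0.77/(uM s) | printed | kept as printed |
| a2 = 4/(uM s) | calibrated | PKB*s brake strong enough to terminate firing crisply |
| a30 = 0.5/s, a5 = 0.026/s | calibrated | quiescent rest with ~1 RasGTP per node |
| a3 = 0.5/(uM s) | rescaled | the RR unit absorbs a factor 100 (see above); the drive a3 RR is unchanged |
| a4 = 0.77/uM | calibrated | gate gain at the resting PIP2 density |
| c1 = 0.027/s | calibrated | slow negative feedback (tau ~ 37 s), the refractory clock |
| c2 = 0.2/(uM s) | calibrated | low resting pool occupancy so firing saturates the pool |
| Ras total = 365,000; PKB pool = 140,000 | calibrated | whole-cell saturating-step peaks ~165,000 RasGTP and ~275,000 PKB*s |

The calibration targets were only resting per-node counts, the saturating
peaks, monostable return to rest after adaptation, and crisp pulse
termination; no acceptance statistic was used. Under these defaults a
saturating uniform step fires the whole cell with the RasGTP peak ~11 s
after onset, activity dies down as RR adapts, and removal returns the cell
to rest within ~20 s.

Excitability under this calibration lives on the *drive* axis: the
threshold is in RR (the response doubles ~50-fold when the drive crosses
~0.1 uM), consistent with the picture that stimuli act by lowering the
activation threshold, while RasGTP seeding at basal drive decays
gradedly - the PKB*s brake exceeds the maximal gate gain at rest.
Spontaneous activity in the stochastic system arises from coincident
fluctuations (a G_bg molecule raising the local readout while the local
PKB*s count dips).

One published behavior does not reproduce under the printed inhibitor
kinetics: the double-pulse refractory curve. The inhibitor excess left by a
short pulse deactivates through the combinatorial `[I*]([I*]-1)` channel,
which near the tiny basal I* level decays hyperbolically and effectively
never resets within 100 s, while the G_bg excess decays in ~10-20 s; the
net suppression of a second response is therefore nearly delay-independent
and the measured recovery curve plateaus around 0.5-0.75 instead of
climbing from ~0 to ~1 with a ~50-s half-time. The package reports what the
model produces.

Threshold perturbations (an extra PIP2 sink, attenuated PKB activation, or
basal/apical asymmetry of the PKB*s-mediated inhibition) are supported as
model transforms and raise activity / localize wave initiations basally as
expected.

## 6. Desk scales, numerical choices, degenerate inputs

*Copy-number scaling.* Combined-model stochastic runs at full counts are
dominated by diffusion of the ~400k inhibitor molecules at D = 20 um^2/s
(tens of millions of events per simulated second). All parameter
constructors accept a `scale` argument implementing the standard
system-size transform - totals x s, bimolecular rate constants / s - which
preserves every concentration-level rate exactly and multiplies the event
rate by `s`, at the cost of `1/sqrt(s)` more relative noise. The package's
standard desk scale is `s = 0.1` on a coarse mesh (`h_max` 0.75-1.2 um,
~350-900 nodes).

*Inhibitor placement at desk scale.* Under spatially uniform protocols the
inhibitor field is uniform, and its diffusivity only spatially averages
fluctuations; uniform-stimulus desk runs therefore use a membrane-local
inhibitor with small D (and `volume_ratio = 1` so the adaptation
proportionality stays exact). Gradient runs keep the fast global inhibitor,
at reduced copy numbers.

*Initialization.* `equilibrate_state()` draws the receptor total from its
cell-to-cell Gaussian, seeds basal G_bg/G_a2/I* directly, relaxes the
mean-field system to its resting point, and scatters the totals
multinomially over each species' localization nodes in proportion to nodal
volume (largest-remainder rounding where determinism is required).
Stationary-statistics windows discard a 30-s settling phase.

*Sector-pooled gradient readouts.* Front/back response-regulator levels
under gradients are evaluated by aggregating excitor and inhibitor counts
over angular sectors before applying the algebraic readout; pooling first
keeps the sector-level comparison clear of the single-molecule rectification
described above.

*Seeded wave fixtures.* At desk scale, seeded activity regions are
extinguished by the strong PKB brake within a few node-spacings, so
collision fixtures verify no-crossing rather than long-range propagation;
wave statistics on coarse meshes under-resolve fronts narrower than the
node spacing.

*Ties, clamps, degenerate inputs.* Obtuse-tetrahedron jump rates clamp to
zero with a logged count; the difference readout clamps at zero; the
PKB pool term clamps at zero if a voxel transiently exceeds its pool share
by diffusion; zero-propensity states simply advance to the horizon; a
zero-magnitude perturbation leaves the model bit-identical; reaction
channels hit by floating-point boundary rounding re-draw instead of firing
a zero-propensity channel.

*Determinism.* Identical (model, mesh, seed, protocol) give bit-identical
trajectories; replicate runs derive sub-streams from the replicate index.

## 7. What the tests show, and what they do not

The synthetic fixtures (voxel chains with closed-form finite-volume hop
rates, birth-death processes, two-species toys, seeded wave collisions,
moving-disk activity patterns) exercise exactness, conservation,
stationarity and the analysis pipeline against independent oracles; the
mean-field ODE backend serves as the large-copy-number oracle for the
module kinetics. Desk-scale stochastic experiments reproduce the full-
scale *statistics* only up to the `1/sqrt(scale)` noise inflation and the
coarser spatial resolution, and say nothing about real cells: no
cytoskeleton, no moving boundary, a rigid idealized geometry, buffered
ligand and phosphate fields, and calibrated rate-constant magnitudes where
the published table was unusable. Wave statistics on coarse meshes
under-resolve fronts narrower than the node spacing.

Problem sizes used by the shipped checks: receptor-noise runs use the
full-scale mesh (~5,400 nodes, 70,000 receptors, 150-s stationary windows,
5 replicates); scheme comparisons and refractory curves run at scale 0.1 on
~350-900-node meshes; sampler-exactness checks use 5,000 replicate pairs on
two-voxel fixtures.
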