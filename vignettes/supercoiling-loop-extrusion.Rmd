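---
title: "Supercoiling-driven loop extrusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercoiling-driven loop extrusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(supercoilex)
```

## The physical picture

Cohesin forms chromatin loops, but whether and how it is powered remains
debated. supercoilex implements a motor-less proposal: a transcribing
RNA polymerase, working together with a topoisomerase that removes the
positive half of its twin supercoiling domain, continuously injects
negative supercoiling into the loop held by a cohesin ring. Supercoiled
fiber is compacted and carries torsional energy; torsionally relaxed
fiber outside the loop does not. Whenever the ring advances, relaxed
fiber flows into the loop and dilutes the supercoiling, lowering the
energy — so the ring is pushed outward along the energy gradient, and
the loop grows. Friction between the ring and the fiber (`gamma_c`)
controls how fast supercoiling escapes through the ring by axial
rotation, and with it the level of supercoiling the loop can hold.

The package provides two complementary implementations:

* a bead-spring Brownian-dynamics model of the full system (fiber, ring,
  motor, moving nicks), with topology analytics (twist, writhe, linking
  number, contact maps), and
* a one-dimensional continuum model: Fickian diffusion of supercoiling
  density on the growing loop, a source at the transcription site, a
  semipermeable moving boundary at the ring, and deterministic
  overdamped motion of the boundary down the supercoiling-energy
  gradient, with least-squares fitting of its two parameters
  (`D_sigma`, `K`) to simulated trajectories.

## The fiber model

One bead is 10 nm of chromatinized fiber carrying 400 bp; the default
closed chain of 150 beads represents a 60 kbp loop domain, and the
relaxed linking number is taken as 40 turns per bead. The potentials
are:

* harmonic bonds (`bond_k = 100 kT/sigma^2`, rest length 1 sigma); the
  published description states only a "strong" bond, so the constant is
  a package default;
* purely repulsive excluded volume (WCA, `epsilon = 1 kT`) between all
  non-bonded bead pairs;
* Kratky-Porod bending, `K_b (1 - cos theta)` with `K_b = 5`, which
  gives a persistence length of about 50 nm;
* a twist potential between consecutive periaxial frames.

Torsional stiffness needs a material frame. Each backbone bead carries
one periaxial virtual bead at `r_p = 0.5 sigma` from the axis. The
virtual beads have no excluded volume and only hydrodynamic drag; the
twist angle of a bond is the signed rotation, about the bond direction,
carrying one periaxial offset onto the next (a dihedral of the
four-point quadruple). The twist potential is `C (1 - cos dphi)` with
`C = 50 kT`: harmonic with spring constant `C` to second order, chosen
so the torsional persistence length is of the same order as the bending
persistence length, but with a torque that is continuous across the
angle wrap (a plain harmonic in the wrapped angle kicks the chain with
discontinuous +/- pi C torque whenever a bond slips a full turn, which
destabilizes long runs; the textbook harmonic form remains available
via `torsion_form = "harmonic"`).

The periaxial attachment is deliberately *soft*: a stiff radial tether
(`tether_k = 600`, about 4% radial fluctuation) plus a perpendicularity
penalty (`perp_k = 100`) keep the virtual bead on a ring around the
local chain axis while leaving the azimuthal angle — the twist degree
of freedom — free. All forces are exact gradients of the total
potential, so the overdamped dynamics satisfies detailed balance. We
first tried the seemingly cleaner alternative of a hard projection
constraint with the frame evolved as a pure angle; it breaks
fluctuation-dissipation balance (backbone noise enters the twist
coordinate kinematically, with no matching dissipation) and overheats
the twist bath by an order of magnitude. The all-gradient form has no
such pathology.

Topological bookkeeping uses two estimators. The exact Gauss linking
number between the backbone polygon and the closed curve of periaxial
beads is a true topological invariant: in a closed torsion-active fiber
it is conserved to floating-point precision over arbitrarily long runs.
The decomposition into twist (sum of bond dihedrals) plus writhe (exact
segment-pair Gauss integral) reproduces the invariant within a
discretization scatter of roughly a quarter turn at 40 beads — the
discrete White identity is exact only up to vertex corrections of order
bend x tilt. Tests therefore check conservation on the invariant and
the identity at its documented scatter.

## Cohesin ring, loading, friction

The ring is a closed chain of 14 beads (10 nm each) with the fiber's
bond, bending and excluded-volume forms. Loading is pseudo-topological:
the fiber is locally folded into a hairpin near the loading bead, the
opened ring is placed so that both strands pierce its disc in opposite
directions, and the construction is healed by a staged relaxation
(backbone first with torsion off, then the full model from a freshly
relaxed frame field). The result satisfies the defining invariants —
ring-fiber Gauss linking number zero, one `+1` and one `-1` disc
piercing — which the tests check with an independent ray-triangle
oracle. The enlarged excluded volume (3 sigma) between ring beads and
the loading bead represents the polymerase body and prevents the ring
from sliding off backwards.

Friction is imposed by raising the drag of the threaded fiber bead on
each embraced arm *and* of its periaxial partner to `gamma_c`
(`single_threaded_bead = TRUE` selects the one-bead variant; the
published description is ambiguous on this point). Threaded beads are
identified per arm as the fiber bead nearest the ring's best-fit plane
among beads inside the ring radius, ties to the lower index. After
loading, the detector anchors to the previous boundary beads
(continuity window of 6 beads): other parts of a crowded chain routinely
wander near the ring plane, and an unanchored detector would teleport
the loop boundary. A completion or escape verdict must persist for 500
consecutive steps before the run terminates.

## Motor and moving nicks

The motor rotates the loading bead's periaxial frame about the local
tangent at exactly constant speed — one rotation per 90 time units,
i.e. 10 rotations per second at the viscosity calibration below. The
frame is kinematically driven while the motor grips it (it does not
respond to torsional torque), which guarantees the constant-speed
boundary condition. Rotating one frame creates a twin domain: negative
twist in the downstream bond and positive twist upstream. The
co-localized topoisomerase is modelled by co-rotating the upstream
bond's torsional reference, so only the negative flux propagates. The
cumulative rotation count is tracked exactly. On a torsionally clamped
fiber every injected rotation is stored, and the summed twist angles
track the counter to 1%. On a free closed circle, by contrast, the
co-rotating reference acts as a topoisomerase sink once the twist has
diffused around, so the stored excess saturates far below the injected
count — which is exactly the uniform-friction calibration behaviour (no
accumulation of supercoiling).

Moving nicks sit one bond outside each loop boundary: those bonds lose
their torsional spring (free axial swivel — the backbone is not cut),
so supercoiling that crosses the high-drag threaded bead unwinds
immediately, standing in for topoisomerase activity at domain borders.
When a nick moves on, the abandoned bond re-engages with its reference
reset to the instantaneous angle, so no stored torsion remains outside
the loop and fiber entering the loop enters relaxed.

## Integration and time calibration

The integrator is first-order overdamped Langevin with per-bead drag:
`dx = (dt/gamma_i) F_i + sqrt(2 kT dt / gamma_i) xi`. One simulation
time unit maps to the Stokes' time of a 10 nm bead,
`6 pi eta sigma^3 / kT = 4.5 us x eta_rel`; the extrusion calibration
uses `eta_rel = 240` (1.08 ms per time unit), so that 10 polymerase
rotations per second is one rotation per 90 time units.

The default step is `dt = 5e-4` with 180,000 steps per rotation. The
product `dt x steps_per_rotation = 90` time units is validated whenever
the motor is enabled, and the coarser pairing `0.0025 x 36,000`
satisfies the same identity; a first-order integrator, however, needs
the smaller step — the stiffest twist normal mode has rate
`4C/(gamma r_p^2)` and becomes marginal at `dt = 0.0025` (an inertial
engine would tolerate it). Two safety nets bound rare near-singular
configurations (deep excluded-volume overlaps during loading, twist
lever arms collapsing at sharp kinks): per-term torsional force caps and
a permanent global per-particle force cap (150), which at the default
step engage only at Boltzmann-negligible energies. If the cap is
disabled and a displacement exceeds half a bead diameter, the run stops
with an instability error.

## Analysis choices

* **Loop metrics.** Arm sizes count beads from the loading bead to each
  threaded bead along the loop; loop twist and writhe are computed on
  the open sub-chain through the loading bead (open Gauss integral, no
  artificial closure), and `dLk = dTw + dWr` by construction.
* **Persistence length** is fitted through the origin to the tangent
  correlation over separations of 1-2 beads, after discarding the first
  half of the run (the chain starts straight). Longer separations are
  excluded on purpose: excluded volume makes the correlation of a
  self-avoiding chain decay slower than exponentially, and including
  them inflates the estimate well beyond the local decay constant that
  defines the persistence length.
* **Contact maps** threshold pairwise distances at 2.5 sigma (no value
  is published; this spans nearest non-bonded approach to about one
  plectoneme diameter), average within runs and then across runs.
* **Extrusion rate** is the least-squares slope of loop size over time,
  converted with 400 bp per bead and the Stokes'-time calibration.

## The continuum model

The solver state is the linear linking density (turns per bead) on a
unit-bead grid spanning the loop `[0, x_c]`:

* interior: explicit diffusion with `D_sigma = 1.6 beads^2/tu` (time
  step `dtau = 0.01`, CFL-guarded);
* source at `x = 0`: 1/90 turns per time unit;
* boundary leak: flux `D_c lambda(x_c)` with
  `D_c = D_sigma gamma_R / gamma_c`, into an absorbing exterior (the
  moving nicks relax everything outside);
* boundary motion: `dx_c/dtau = -(1/gamma_c) du/dx_c` with
  `u = K dLk^2 / x_c` and `K = 3.4e3` (halved per arm: the 1-D model
  lumps the two fibers passing through one ring);
* dilution: cells entered by the boundary start relaxed.

Two normalization choices deserve comment. First, the published energy
is written as a bare quadratic `K dLk^2`; at fixed `dLk` that form
exerts no force on the boundary, contradicting the stated mechanism
(the energy must *drop* when relaxed fiber dilutes the loop), so the
default is the per-length form `K dLk^2 / x_c` and the bare quadratic
sits behind `energy_form = "plain"`. Second, the literature value of
the supercoiling-energy constant is quoted per base pair while the
model works in bead units; we treat `K` as the fitted bead-unit
constant. The optional extended functional adds the loop-stiffness
penalty and entropic looping cost `8 l_p / x_c^2 + c log(x_c)`
(with the fitted `K = 1550`, `c = 0.03`).

`continuum_fit()` estimates `(D_sigma, K)` (optionally `c`) by
Nelder-Mead on log-parameters, minimizing the concatenated residuals of
modelled loop size and linking number against all trajectories of one
friction setting, each series normalized by its spread. Identifiability
is best at intermediate friction, where the leak (through `D_c`) shapes
the observables; parameter-recovery tests run there.

## Known limitations, and what the tests do and do not show

* The published figure set for this mechanism is not internally
  consistent under any Fickian reading we could construct: relaxing
  ~87% of injected rotations through a boundary of permeability
  `D_sigma/gamma_c` at the highest friction requires a boundary density
  that contradicts the quoted total linking numbers by an order of
  magnitude, and a boundary mobility `1/gamma_c` makes the low-friction
  solve complete *faster* at the quoted linking-number levels, not 15x
  slower. The package implements the equations as stated and reports
  what they produce; the acceptance checks that depend on the
  irreconcilable figures fail at face value rather than being tuned.
* For the same reason, the desk-scale Brownian-dynamics runs (40 beads,
  a few motor rotations) are dominated by entropic loop growth and
  boundary diffusion: extrusion is directional and low friction is
  visibly noisier — both tested — but the friction ordering of
  completion times does not reproduce at this scale, and tests do not
  assert it.
* Passing tests show that the implemented mechanics is thermodynamically
  consistent (exact gradients, detailed balance, topological
  conservation) and reproduces the calibrations and trends stated
  above on synthetic systems. They do not validate the model against
  experimental chromatin data, which is outside the package's scope.
* Hydrodynamic interactions, sequence-dependent fiber properties,
  CTCF stalling and nucleosome-resolution geometry are not modelled.

## Problem sizes used by the shipped checks

Module tests run seconds-long simulations (10^4-10^6 steps at 12-40
beads). The acceptance computations use three seeds of 1.2 x 10^6 steps
on a 60-bead free fiber for the persistence length, and the full
150-bead continuum solves for the linking-number, relaxation and rate
figures. The full-scale Brownian-dynamics production runs (150 beads,
hundreds of motor rotations per trajectory, CPU-weeks in the original
study) are intentionally not part of any automated check; the shipped
default configuration reproduces their setup for users who want them.
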