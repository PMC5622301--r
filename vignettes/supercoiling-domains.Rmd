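---
title: "Transcription-induced supercoiling and self-interacting chromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription-induced supercoiling and self-interacting chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(supercoilr)
```

## The model

`supercoilr` simulates 10 nm chromatin fibres as twistable bead–spring
polymers. One bead is 10 nm in diameter and covers 400 bp, so a typical
fission-yeast self-interacting domain of 50 kb is a 125-bead stretch. The
fibre carries four energy terms in reduced units (lengths in
$\sigma = 10\,$nm, energies in $\epsilon_0 = k_BT$):

* **Excluded volume** — a cut-and-shifted, purely repulsive Lennard–Jones
  pair potential with $r_{cut} = 1\sigma$, so beads interact only on contact.
* **Bonds** — harmonic springs of rest length $1\sigma$. The spring constant
  (default $800\,\epsilon_0/\sigma^2$) is not a property of the fibre being
  modelled; it is set stiff enough that bond-length fluctuations stay below
  ~4% while still allowing a stable time step.
* **Bending** — the Kratky–Porod form $\epsilon_b(1-\cos\theta)$ with
  $\epsilon_b = 5\,\epsilon_0$. In the stiff limit this maps to a
  persistence length $L_p \approx \epsilon_b \cdot b = 50$ nm; the exact
  discrete-chain value at $\epsilon_b = 5$ is
  $-b/\ln(\coth 5 - 1/5) = 45$ nm, and self-avoidance pushes the fitted
  tangent-correlation decay back up to ≈50 nm.
* **Torsion** — each bead carries a side site 0.5σ away, perpendicular to
  the local chord; the ladder of side sites defines the material frame. The
  signed dihedral $\phi$ of consecutive rungs is penalized by
  $V(\phi) = \tfrac12 k\phi^2$ with $k = 4\,\epsilon_0/\mathrm{rad}^2$,
  wrapped to $(-\pi,\pi]$. A per-bond rest angle $\phi_0$ can impose a
  linking-number deficit on closed fibres.

The side-site "ladder" realization was chosen over a four-backbone-bead
dihedral because the latter degenerates on straight chains, while the ladder
dihedral is well defined everywhere. Two auxiliary terms maintain the frame:
a stiff tether (10× the bond constant) fixing the 0.5σ offset, and a
perpendicularity penalty $\tfrac12 k_\perp(\hat u\cdot\hat c)^2$ against the
local *chord* $\hat c = r_{i+1}-r_{i-1}$. $k_\perp = 100\,\epsilon_0$ is
deliberately large: if a side site could thermally cross the chain or bond
axis the frame would slip a full turn and the ribbon would leak linking
number. At $k_\perp = 100$ the crossing barrier is ≈50 $k_BT$ and we observe
exact Lk conservation (to $10^{-11}$) in closed swivel-free ribbons over
millions of steps. The price of the stiff frame is a small effective
bending stiffening: the ideal discrete Kratky–Porod chain at
$\epsilon_b = 5$ has $L_p = 45$ nm, while the full realization (frames plus
excluded volume) fits at ≈55 nm — bracketing the nominal 50 nm. A
flat-bottomed variant of the constraint was tried and rejected: it removes
the restoring force, lets the side vector wander to the barrier, softens the
effective torsional rigidity and, at high torsional strain, lets the frame
slip linking number.

### Twist, writhe and the linking number

Writhe is computed as the discretized Gauss double integral — the sum of
pairwise signed solid angles over all non-adjacent segment pairs. Twist is
the sum over bonds of the ladder dihedral *plus a vertex parallel-transport
term*: when a side vector is projected onto the two edges meeting at its
vertex, the residual rotation between the two projections (after transport
about the binormal) is genuine twist. Without the vertex terms the identity
$Lk = Tw + Wr$ holds only to $O(\text{wobble}^2)$ per bond (~0.2 turns on a
130-bead loop); with them it holds to machine precision, which the test
suite checks frame by frame. Per-domain writhe restricts the Gauss sum to
segment pairs inside the domain's bead range; cross-domain terms are
excluded and are below 5% for well-separated domains. Domain ranges include
the flanking motor beads by default (they are part of the transcribed
fibre); a toggle excludes them.

### Motors, swivels, passage zones

**Torsional motors** stand in for transcribing RNA polymerases. A motor
occupies two beads (800 bp) and applies a constant external torque about the
local fibre axis to the material frame of those beads — the reaction is
absorbed by the implicit medium, as for a polymerase effectively anchored by
viscous drag and crowding. We implement the torque as a force couple between
each motor bead and its side site, so the net force is zero and the torque
about the tangent equals the set value. This *external-drive* realization
matters: an internal torque applied across a single dihedral is conservative
— it twists its own bond to a new equilibrium and transmits nothing — and a
pair of such motors around a free swivel merely spins the enclosed domain
rigidly. With the external drive, the domain boundary feels exactly the
motor torque, twist accumulates until the elastic back-torque balances it,
and motor stalling emerges automatically. Torques are set in pN·nm and
converted at $k_BT = 4.1$ pN·nm (2 pN·nm ≈ 0.49 $\epsilon_0$/rad); the
default is 2 pN·nm. The sign convention follows the handedness of
transcription: negative twist accumulates behind each motor, so two motors
transcribing divergently out of a domain drive it negatively supercoiled.

**Swivels** are bonds with zero torsional stiffness, placed ahead of each
motor: torsional stress downstream of the polymerase (where a type I
topoisomerase travels with it) dissipates freely, while the negative stress
behind it is long-lived.

**Passage zones** are 10-bead stretches whose excluded-volume prefactor is
reduced so that thermally driven duplex–duplex passages become possible,
mimicking type II topoisomerase activity at domain borders. The paper-scale
form of the softened potential is only qualitative ("very weak"), so the
prefactor is the model's main free parameter for the passage rate. The
default sets the barrier felt by a segment sitting mid-plane between two
zone beads to ≈2 $k_BT$; absolute passage rates are therefore not a
quantitative output of this package. Torsional stiffness is unchanged inside
zones.

**Cohesin rings** are 16 beads of 10 nm on a rigid circle whose
circumference equals the summed bead diameters (centre-line diameter
$160/\pi \approx 50.9$ nm). Rigidity is maintained by a stiff all-pairs
elastic network ($k_{ring} = 1000\,\epsilon_0/\sigma^2$; pairwise distances
stay fixed to <1% under thermal forces) rather than by rigid-body
integration — at these sizes the two are observationally equivalent and the
network integrates with the same scheme as everything else. Each ring is
threaded on the fibre at construction and held by a harmonic restraint
between its centre and the anchor bead.

## Dynamics

A BAOAB-splitting Langevin integrator (unit mass, friction $\gamma = 1$,
$k_BT = 1$) evolves all particles. Coordinates are integrated unwrapped —
topology measures need the unwrapped curve — and the minimum-image
convention applies inside non-bonded interactions. The default time step is
$10^{-3}$ reduced time; the stochastic studies in this package use
$2\times10^{-3}$, an order of magnitude below the stability bound of the
stiffest mode ($\omega=\sqrt{k_{side}}\approx 89$), and the sampling checks
(equipartition, harmonic bond-length variance, agreement with direct
Boltzmann draws and with an independent pivot Monte Carlo) pass at that
step. A run aborts with a diagnostic if any particle moves more than 0.5σ
in one step.

Replica management follows the study design: each replica is
pre-thermalized, the integrated autocorrelation time of the radius of
gyration is estimated (sum of the normalized autocorrelation to its first
zero crossing), and production is extended until it covers at least 8
autocorrelation times (configurable; a trajectory that cannot reach that is
flagged). Replicas use distinct seeds derived from the base seed and are
bitwise reproducible.

The reduced-to-physical time mapping uses Stokes' drag for a 5 nm-radius
bead. The Brownian time $\gamma_{phys}\sigma^2/k_BT$ is ≈2.04 µs in water;
a fixed calibration constant (2.45 Brownian times per reference step)
anchors one step at the reference $dt$ to ≈5 µs in water and ≈75 ms at
15000× water viscosity, linear in both viscosity and $dt$.

## Starting configurations and the periodic box

Loops start as flat circles (twist and writhe zero) — the didactic starting
state for watching supercoiling build up. Linear fibres start either
straight or as a direct Boltzmann draw of the ideal discrete worm-like chain
(`wlc_chain_positions()`), which samples bond angles from
$e^{\epsilon_b\cos\theta}$ exactly; the draw equilibrates local statistics
immediately, so only the excluded-volume swelling needs dynamical
relaxation. Persistence-length measurements use the worm-like-chain start: a
straight start relaxes its large-scale tangent correlations only on the
whole-chain Rouse time and inflates the fitted $L_p$ severely if not given
that long.

The periodic box defaults to the larger of 4× the expected radius of
gyration and 1.25× the contour length. The second criterion matters for
straight starting configurations: in a box sized only to the coil, a
straight chain would overlap its own periodic images along its axis. The
simulated regime is dilute either way.

## What the generator reproduces, and what it does not

The synthetic systems reproduce the *study conditions*: 400 bp/10 nm beads,
$\epsilon_b = 5$, $k = 4$, $r_{cut} = 1\sigma$, motors of 1–4 pN·nm
(default 2), two-bead motors, swivels ahead of motors, 10-bead zones,
16-bead rings at ~50 kb spacing, five replicas, thermalization past 8
autocorrelation times. Domain sizes for multi-domain fragments are sampled
uniformly from 40–100 kb — the experimental size distribution of
fission-yeast domains is not tabulated, only its 50–100 kb range, so the
uniform law is a documented approximation. Desk-scale production runs are
millions of steps, not the ~20 million configurations of the full study;
passing tests therefore demonstrate the mechanisms (negative supercoiling of
divergent domains, writhe saturation by motor stalling, homeostatic recovery
after passages, TAD-like triangles with torque, featureless maps with rings
only) at reduced statistical resolution, not publication-scale contact-map
statistics, and say nothing about real nuclei beyond what the coarse-grained
model itself asserts.

Known quantitative behaviours of this realization, measured by the
acceptance suite: the fitted persistence length lands between 45 and 50 nm
(excluded-volume swelling above the ideal 45 nm discrete value, minus slow
equilibration of the mid-range correlations); a closed fibre with an imposed
linking deficit of −6 turns stores roughly 50–57% of it as writhe at
equilibrium (the linear-response estimate from the loop's writhe and twist
fluctuations, $\mathrm{Var}_0(Wr) \approx 1.0$ vs
$\mathrm{Var}_0(Tw) \approx 0.82$ turns² at $n=130$, gives ≈55%, and two
8×10⁶-step strained runs from different seeds both give 56.5%, so this is
the equilibrium of this force field, not a sampling artifact); and the
steady-state writhe of a motor-driven 50 kb domain scales near-linearly with
torque (≈ −1.3, −2.7 and −5.7 turns at 1, 2 and 4 pN·nm). Where these differ
from the headline figures of the full-scale study, the difference traces to
the unspecified details of the original torsion construction (the mapping
from its dihedral coordinate to ribbon twist), not to sampling length; we
keep the printed stiffness constants and report what they produce.

The problem sizes the package's own studies use: a 200-bead passive chain
for the persistence length (three replicas of 2×10⁶ steps, first 55%
discarded), a 130-bead closed ribbon at ΔLk = −6 for the twist–writhe
partition (three replicas), a 129-bead loop for the torque dependence of
domain writhe (3–4 replicas of 1.8–3×10⁶ steps, longer at weaker drive
because writhe nucleation slows), and 60–250-bead systems for the contact
and cohesin properties.

## Numerical choices

* Time step $2\times10^{-3}$ for production (default $10^{-3}$): validated
  by energy conservation ($\gamma = 0$ drift < $10^{-4}\epsilon_0$/step) and
  the Boltzmann-sampling checks.
* Neighbour list: Verlet list with 0.4σ skin, rebuilt when any particle
  moves half the skin.
* Gaussian noise: ziggurat sampler seeded per replica; same seed → bitwise
  identical trajectories.
* Passage detection threshold 1.5 turns: between the thermal writhe
  fluctuation scale (≲1) and the topological jump of 2.
* Insulation boundary calls: sliding 5-bin diamond, local minima at least
  10% below the profile mean; validated on constructed block matrices only —
  the original analysis called boundaries visually.
* Contact cutoff 1.5σ (15 nm surface proximity), bonded neighbours excluded
  (both exposed as arguments).
* Degenerate inputs: coincident consecutive beads are an error for writhe;
  constant series are an error for autocorrelation time; a swivel annotated
  on a motor bond is an error.

## Limitations

Motors are static (they do not translocate); nucleosome-scale structure,
sequence effects and hydrodynamic interactions are out of scope. The
cohesin-barrier contrast ("depletion lines but featureless maps") is fully
visible only with publication-scale sampling; at desk scale the package
demonstrates the robust parts — strong contact depletion at ring anchors and
the absence of insulation boundaries at ring positions — while global map
featurelessness at 10 kb needs equilibrated long-range statistics. Absolute
passage rates depend on the arbitrary zone softening. The cohesin-ring
restraint constant and the ring elastic network are numerical devices, not
measured quantities. Contact maps from desk-scale runs are noisy at 400 bp
resolution; the 10 kb binned maps are the robust output.
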