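---
title: "Modeling oxidative folding with a reactive coarse-grained engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oxidative folding with a reactive coarse-grained engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxfold)
```

## The problem

Disulfide bonds between cysteine sulfurs are a major determinant of the
folding of many peptides and small proteins, yet conventional molecular
dynamics keeps the covalent topology fixed: a trajectory started with free
thiols can never form an S--S bond. `redoxfold` implements a reactive
protocol that lets disulfides form (and, optionally, break) *during* a
running simulation while perturbing the dynamics as little as possible, and
couples it to the analysis statistics used to characterize oxidative
folding: disulfide isomer bookkeeping, kinetic footprints (first- versus
second-bond formation times), radius of gyration, ensemble RMSD under
optimal superposition, and NOE-restraint violation scores.

The reference system throughout is a guanylin-like peptide: 15 residues
with four reactive cysteines at positions 4, 7, 12 and 15. Four cysteines
admit exactly three complete pairings, so every fully oxidized product is
one of three isomers: `{4-7, 12-15}` (isomer 1), `{4-12, 7-15}` (isomer 2,
the biologically active pattern), or `{4-15, 7-12}` (isomer 3). Which
isomer forms is decided kinetically, by which thiol pair happens to meet
first in the disordered chain — this is the behavior the protocol is
designed to capture.

## The reactive protocol

A cysteine able to react is typed `CYR`: a deprotonated but overall
neutral thiol. The single change to the force field is that the pairwise
Lennard-Jones term between every pair of `CYR` sulfurs is switched off
("masked"), removing the repulsive wall that would otherwise keep two
sulfurs from approaching to bonding distance. Everything else is the
standard, unaltered potential. A run has three stages:

1. **Equilibration.** Conventional dynamics, mask inactive.
2. **Oxidative folding.** The mask is active and the run proceeds in
   segments (default 1 ns) with frames stored every 1 ps. Before each
   segment a restart point (positions, velocities, RNG state) is recorded.
   After a segment, its stored frames are scanned in order:
   - **Capture.** The earliest frame where any reactive S--S distance is
     at or below the capture radius $r_c = 2.5$ Å flags a potential bond.
     Ties within one frame are broken by smallest distance, then by the
     lexicographically smallest pair, so detection is deterministic.
   - **Gate.** Each contact frame makes a Bernoulli decision: a uniform
     draw is accepted if it falls below $p_0$. With the default $p_0 = 1$
     every thiol encounter is productive; lowering $p_0$ (the
     reduced-reactivity protocol uses $p_0 = 0.001$ per contact frame)
     slows the effective reaction rate relative to the conformational
     dynamics without touching the force field. Waiting times to
     acceptance are geometric by construction.
   - **Rewind.** The segment is re-propagated from its restart point to
     the crossing frame and the replay is verified *bitwise* — the state
     of the system at the precise moment of the crossing is reproduced
     exactly, not approximately. Any divergence is a fatal error.
   - **Ramp.** From the crossing state, artificial harmonic restraints
     imitating the disulfide are switched on at 1/200 of full strength
     and ramped stepwise, $\alpha = k/200$ with one increment per 10 ps
     window, over a 2-ns segment: the S--S distance toward
     $r^0_{SS} = 2.038$ Å with $k_d = 166$ kcal/mol/Å², the C-S-S and
     S-S-C angles toward 103.7°, and a C-S-S-C dihedral toward ±90°. The
     restraint energy is $\alpha k (x - x_0)^2$ (no 1/2 factor), matching
     the convention of the bonded terms it will become.
   - **Bond.** The restraints are replaced by permanent bonded terms with
     identical targets and full force constants; both residues are
     relabelled `CYX`, leave the reactive registry, and all their masked
     LJ interactions return to normal.
   Only one disulfide forms per segment; the loop restarts after each
   bond and ends when no reactive pairs remain or the folding budget is
   exhausted (a run with leftover reactive sites completes with status
   `"unbonded-remaining"`).
3. **Extension.** Conventional dynamics of the fully bonded species.

An optional reverse step models reduction (e.g. by glutathione): at each
segment boundary every existing disulfide is dissolved with probability
$p_r \times \mathrm{exposure}$, restoring both sulfurs to the reactive
registry. $p_r$ is meant to be small compared with $p_0$ so that only
long-lived trapped states are rescued; the exposure proxy (`constant` or
`inverse_neighbors`, a contact-count measure around the bridge midpoint)
stands in for solvent accessibility.

### Why the protocol is "perturbation-free"

Three mechanisms keep the reactive machinery from disturbing the physics:

- Monitoring happens on *stored frames only*; the integrator never sees
  the controller. Up to the first accepted capture, a controlled run is
  bitwise identical to a plain run of the same masked topology and seed
  (asserted in the tests).
- The gate consumes a separate RNG stream (R's generator) from the
  dynamics noise (an own xoshiro256++ stream stored per frame), so
  decisions never shift the thermal noise sequence.
- The fully ramped restraints and the installed generic bond are *exactly*
  equivalent: the permanent terms are built from the same parameter set
  the ramp used, and the LJ pairs that the new bond excludes (the 1-2
  S--S pair and the 1-3 backbone--sulfur pairs) are already masked while
  the ramp is active. The replacement is therefore energy-neutral to
  floating-point accuracy on a two-cysteine system. With more than two
  reactive cysteines an exact global statement is impossible in
  principle: bonding a pair re-enables the previously masked standard LJ
  between the newly bonded sulfurs and the remaining reactive ones, a
  change inherent to the protocol itself, not to this implementation.

One wrinkle in the ramp schedule deserves a note: the scale factor
satisfies $\alpha(0) = 0$ and $\alpha(200) = 1$ exactly, but the first
window actually *applied* uses $k = 1$, i.e. $\alpha = 1/200$ — the ramp
runs from 1/200 to 1, not from 0.

## The coarse-grained representation

The controller logic is representation-agnostic; this package pairs it
with a deliberately small vacuum model so that the full protocol runs at
desk scale:

- One backbone bead per residue (110 amu), bonded at 3.8 Å
  ($k = 100$ kcal/mol/Å²) with soft backbone angles
  ($\theta_0 = 120°$, $k = 2$ kcal/mol/rad²) so the chain stays
  disordered, plus one sulfur bead (32.06 amu) 1.8 Å off each cysteine
  backbone bead. The S--S distance, C-S-S angles and C-S-S-C dihedral of
  a bridge are then all well defined.
- Nonbonded interactions use the sulfur-sulfur LJ form
  $\varepsilon((r_0/r)^{12} - 2(r_0/r)^6)$ with $\varepsilon = 0.25$
  kcal/mol and $r_0 = 4$ Å for all pairs, truncated (not shifted) at
  10.5 Å; 1-2 and 1-3 bonded neighbors are excluded. The truncation
  discontinuity (about 0.002 kcal/mol) is accepted and documented rather
  than hidden by shifting, to keep the pair energy the textbook form.
- `CYR` carries no charge and no special nonbonded parameters beyond the
  mask. An alternative mode (`lj_mode = "shrunk_r0"`) contracts the
  reactive-pair minimum from 4 Å to 2 Å instead of masking; the capture
  radius stays 2.5 Å in both modes.
- There are no periodic boundaries and no solvent; a reflective sphere of
  radius 60 Å (comfortably larger than the 56-Å inscribed-sphere diameter
  a truncated-octahedron cell of this peptide would need, cf.
  `truncated_octahedron_diameter()`) prevents escape on long runs.
- Dihedral parameters for the bridge are not uniquely dictated by the
  coarse model; the default is a single C-S-S-C restraint with
  $k = 3.5$ kcal/mol/rad² and target ±90°, the sign chosen from the
  geometry at ramp entry so the chain is never driven through a 180°
  rotation. Both are configurable.

Units are fixed package-wide: Å, ps, kcal/mol, K, amu, with
$k_B = 0.0019872041$ kcal/mol/K.

## Integration and reproducibility

Propagation uses the BAOAB splitting of Langevin dynamics at
$T = 293$ K with collision frequency $\gamma = 2\ \mathrm{ps}^{-1}$ and
$\Delta t = 2$ fs. BAOAB was chosen for its robustness with stiff
restraints at this step size and its clean limits: at $\gamma = 0$ the O
step is skipped entirely (no RNG consumption) and the scheme reduces
exactly to velocity Verlet, which the tests exploit to verify energy
conservation (relative drift below $10^{-4}$ over $10^4$ steps on a soft
harmonic dimer) and equipartition (kinetic temperature within three
standard errors of 293 K on the chain fixture).

The thermal noise comes from an own xoshiro256++ stream whose 32-byte
state is stored in every frame. Normals are generated by Box–Muller in
pairs within each O step, so the stream state at a frame boundary fully
determines everything that follows: restarting from any stored frame
reproduces the trajectory bit for bit. This is what makes the
rewind-to-crossing step exact. State files serialize coordinates with 17
significant digits (decimal JSON numbers would silently round), so a
write/read cycle is also bitwise.

Degenerate inputs are errors, not silent results: overlapping particles
(within $10^{-6}$ Å), non-finite coordinates after a step (reported with
the step number), restraints referencing out-of-range particles, a ramp
whose S--S distance diverges from target over three consecutive windows,
and replay divergence all stop the run.

## Analysis statistics

- **Isomer bookkeeping.** `enumerate_pairings()` generates all perfect
  matchings ($(n-1)!!$ of them); `classify_isomer()` maps a disulfide set
  to isomer 1/2/3, and a single-bond pattern to `partial` plus the unique
  complete pairing it commits to — with four cysteines one bond always
  determines the isomer, which is what makes one-bond trajectories
  countable in isomer distributions.
- **Kinetic footprint.** Per trajectory, the times of first and second
  bond formation on the folding-stage clock, with ensemble means and
  isomer fractions. In the bundled coarse model the second bond takes an
  order of magnitude longer than the first — the first bridge sharply
  reduces the conformations compatible with the second — and isomer 2 is
  the least frequent product, both qualitative signatures of kinetic
  control.
- **Ensemble RMSD.** Optimal rigid-body superposition (SVD-based
  Kabsch, cross-checked in the tests against an independent closed-form
  quaternion method to $10^{-8}$). The averaging convention for the
  ensemble value is deviation from the *iteratively superposed mean
  structure* (fit all conformers to a reference, recompute the mean,
  repeat to convergence), not the mean of pairwise RMSDs; the pairwise
  matrix is returned alongside for lowest-pairwise statistics.
- **NOE violations.** Per restraint, zero deviation inside
  $[r^{NOE}_{low}, r^{NOE}_{high}]$, $(r - r_{high})$ above,
  $(r_{low} - r)$ below. Ambiguous groups are collapsed *before* the
  bound comparison with the $r^{-6}$ sum over all inter-group pairs,
  $r = (\sum_i r_i^{-6})^{-1/6}$. "Linearly combined and normalized" is
  implemented as the arithmetic mean over restraints — a violation per
  single restraint.

## The synthetic generators

`random_chain()` draws a self-avoiding random walk (fixed 3.8-Å bonds,
3.4-Å hard core between non-bonded backbone beads, clash-checked sulfur
placement, bounded retries) with Maxwell–Boltzmann velocities, as a pure
function of its seed. It emulates a disordered, unfolded starting
ensemble with excluded volume; a clash filter replaces energy-based
screening of candidate conformers, which would require a solvent model.
What it does *not* emulate: side-chain chemistry, sequence-dependent
conformational propensities, hydrogen bonding, or solvent structure. A
passing test suite therefore demonstrates the correctness of the
protocol's mechanics and statistics on this model class — not that the
coarse model reproduces any particular peptide's experimental isomer
ratios or time scales, which depend on an all-atom force field and
explicit solvent outside this package's scope.

`two_bead_system()` (two masked sulfurs) and `four_bead_css_c()` (a
C-S-S-C fragment) are the minimal systems on which the ramp targets are
verified: after a full default ramp at 293 K the final-window mean S--S
distance sits at 2.038 ± 0.1 Å and the mean C-S-S angle at 103.7 ± 3°,
the tolerances being thermal fluctuation at this temperature (the
radial-distribution Jacobian biases the mean distance upward by
$\sim k_B T / (k_d\, r^0_{SS}) \approx 0.002$ Å, far inside the thermal
band).

## Problem sizes and defaults

Desk-scale defaults, chosen once as the package's study conditions: stage
lengths 1 ns / 10 ns (maximum) / 1 ns for the 19-bead guanylin-like
fixture, 1-ns segments, 1-ps frames, the full 200 × 10 ps ramp. At these
sizes one complete folding run is a few million integrator steps; the
bundled acceptance script runs a 20-seed ensemble (all of which form both
bridges well inside the folding budget at $p_0 = 1$). Full-scale
conditions for all-atom studies of this system (100 ns / up to 1 µs /
450 ns) are provided as `stage_preset("reference")` for completeness;
they are not desk-scale.

## Known limitations

- Vacuum coarse-grained chains compact and diffuse faster than solvated
  all-atom peptides; absolute times (and the first/second-bond ratio) are
  model-specific and should be read comparatively, not quantitatively.
- Thiol–disulfide exchange is not modeled as a concerted move; an
  exchange can only happen as a reduction followed by a new oxidation.
- Pair-specific reactivities (e.g. pKa-derived per-pair rates) are not
  built in beyond the single global $p_0$.
- The harmonic dihedral restraint holds one stereoisomer of the bridge
  (+90° or −90°); interconversion during a run is effectively forbidden
  once the full-strength bond is installed.
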