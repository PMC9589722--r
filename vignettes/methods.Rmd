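---
title: "Model and methods: double-basin coarse-grained simulation of ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Enzymes such as adenylate kinase (AdK) alternate between an open
conformation, in which substrates can enter and leave, and a closed,
catalytically competent conformation in which a correctly bound substrate is
tightly caged. A substrate that first associates in a *non-native* pose — the
common outcome of the initial encounter — cannot rearrange inside the closed
cage. `cgbind` implements a residue-level model in which this hypothesis can
be tested quantitatively: repeated opening/closing cycles rescue incorrectly
bound substrates, and a non-natively bound substrate in turn destabilises the
closed state, removing the free-energy barrier to opening.

# The energy model

Each protein residue is one bead at the C-alpha position; ligands are small
rigid bead clusters (five beads for an AMP-like substrate, seven for an
ATP-like one). The total potential has four groups of terms.

**Local (bonded) terms, referenced to the closed structure.** Harmonic
virtual bonds `k_b (r - r0)^2`, cosine-harmonic virtual angles
`k_a (cos t - cos t0)^2`, periodic dihedrals `k_d (1 - cos(p - p0))`, and an
intra-domain elastic network of harmonic distance restraints (constant
`k_enm`, cutoff `enm_cutoff`, longer `enm_cutoff_core` within CORE). Two
numerical choices matter here:

* the cosine-harmonic angle form is used because synthetic reference
  geometries (and occasionally real ones) contain nearly straight
  three-bead stretches, where the usual `k (t - t0)^2` form has a singular
  gradient (it divides by `sin t`);
* dihedral terms are kept only where both flanking reference bends are well
  away from collinearity (`sin > 0.6`); elsewhere the torsional gradient is
  unbounded under thermal motion. Tertiary structure is maintained by the
  contact network and the elastic network, so dropping these terms costs
  little, and both references remain exact strain-free minima because every
  retained local term has the same reference value in the closed and open
  conformers (hinge-spanning terms are excluded by construction).

The elastic network is part of the generic closed-referenced local terms:
without it, a sparsely contacted synthetic architecture melts at 300 K.
Domains therefore move as quasi-rigid bodies about the hinge, which is the
intended regime of a domain-motion model.

**Native contacts.** 12-10 wells
`eps (5 (r0/r)^12 - 6 (r0/r)^10)` for bead pairs in contact in a reference
structure (closest heavy-atom distance below 6.5 Å when atoms are
available, bead–bead distance otherwise; sequence separation at least 3 for
protein pairs). Protein–ligand contacts use `eps_nat = 0.15` kcal/mol;
protein–protein contacts use `eps_pp` (1.2 kcal/mol by default, 1.0 under
the study conditions below).

**The double-basin interface.** Contacts are classified by domain interface
(LID–CORE, NMP–CORE, LID–NMP where present). For each interface the
closed-reference contact sum `V1` and the open-reference contact sum plus an
offset, `V2 = V_open + deltaV`, are mixed through the standard two-state
secular-determinant form

```
V_MB = ((V1 + V2) - sqrt((V1 - V2)^2 + 4 Delta^2)) / 2,
```

which is at most `min(V1, V2)` and smooth everywhere; forces use the
chain-rule weights `dV_MB/dV1` and `dV_MB/dV2`. `deltaV` sets the relative
basin depth (calibrated, below); `Delta` sets the switching barrier and is
chosen so transitions occur on accessible simulation timescales. Intra-domain
contacts and all bonded terms are shared between basins.

**Ligand interactions.** Non-native protein–ligand pairs (residues within
6 Å of a native-contact residue, reference distance at most 10 Å) feel a
Gaussian well `-eps_nnat exp(-r^2 / (2 sigma_nnat^2))` with
`sigma_nnat = 6` Å; `eps_nnat` is the ruggedness dial of the binding
landscape and the central study variable. All remaining pairs repel as
`eps (sigma / r)^12` with `sigma = 5` Å (protein–ligand), 3.5 Å
(ligand–ligand) and 4 Å (protein–protein, prefactor 0.2). Ligands are kept
rigid-like by a stiff harmonic distance network over their first, second and
third neighbours (25 kcal/mol/Å^2 for bonds, half that for the others) —
equivalent in effect to restraining bonds, bends and torsions to reference
values, but with everywhere-bounded forces.

All pair terms are truncated with an energy shift: contacts at `2.5 r0`,
Gaussian wells at `3.5 sigma`, excluded volume at `2.5 sigma`. The largest
shift is below `10^-3` of a well depth, far under `kT`. Protein pairs whose
reference distances exceed 14 Å in both conformers are dropped from the
excluded-volume list (quasi-rigid domains cannot bring them into range).

# Dynamics

BAOAB-splitting Langevin dynamics with unit bead masses, friction
`gamma = 0.25 / tau` and `T = 300 K` (`kT = 0.596` kcal/mol). With
`gamma = 0` the scheme reduces to velocity Verlet. The default step is
`dt = 0.05 tau`: with unit masses the stability limit for the chosen force
constants sits near `0.06 tau`, so the conventional `0.1 tau` (which
presumes beads of roughly 100 atomic mass units) is halved; this is a units
convention, not a change of the physics. The noise stream is counter-based
on (seed, global step index, degree of freedom), so trajectories are
bit-reproducible and a run may be serialized and resumed without altering
the stream.

Restraints available to all drivers: half-harmonic flat-bottom restraints on
group-centroid distances (binding-area confinement, `K = 23.9`
kcal/mol/nm^2, flat radius 8 Å in the studies), best-fit RMSD restraints
(targeted MD, closed-state locks), harmonic umbrella biases on the
conformational coordinate, distance tethers (pose holders), and positional
fixes.

# Reaction coordinates

* `xi = (RMSD_C - RMSD_O) / RMSD_CO` over protein beads, -1 at the closed
  reference, +1 at the open one (Kabsch best-fit RMSDs).
* `Q`, the fraction of formed native contacts of a ligand; a contact counts
  as formed below `1.2 r0` (a smooth logistic variant is provided for
  differentiable analyses).
* Pose coordinates `(R, theta)`: after superposing the CORE beads onto the
  closed reference, `R` is the displacement of the terminal-phosphate bead
  and `theta` the angle between instantaneous and reference
  base-to-phosphate vectors. Both vanish in the native pose.
* Interdomain distances between unweighted domain centroids.

# Enhanced sampling and kinetics

**PaCS.** Cycles of short unbiased replicas; all snapshots plus the
incumbent seeds are ranked by RMSD to the target and the best re-seed the
next cycle, so the best RMSD never rises and no biasing force ever acts.
Stalled cycles trigger a conventional-dynamics relaxation segment.

**Umbrella sampling / MBAR.** 41 windows spanning `xi` in [-1, 1] at 0.05
spacing, force constant 836 kcal/mol, first quarter of each window
discarded (the conventional protocol discards 10 ns of 40 ns). Windows are
seeded by two directional sweeps — closed-to-open and open-to-closed, each
window starting from its predecessor's final state — and both sweeps'
samples are pooled, so hysteresis between the two transition directions is
exposed rather than hidden (seeding every window from the nearest
reference instead leaves visible start-state artefacts in the profiles).
The window free energies minimise the convex multistate-reweighting
objective (BFGS with the analytic gradient) and are polished by
self-consistent sweeps to a relative tolerance of `1e-7`; profile
uncertainties come from a block bootstrap within windows. The solver is
validated against the plain fixed-point iteration and against closed-form
profiles. The coordinate may be restricted to one mobile domain plus CORE
to profile a single interface's opening.

**MFPT estimation.** First-passage times are right-censored at the
trajectory horizon. Under the exponential (two-state barrier crossing)
model the maximum-likelihood estimate is total observation time divided by
the number of events; confidence intervals use a percentile bootstrap over
records. Open/close cycle counting uses two-threshold hysteresis at 30% and
70% of the closed-to-open interdomain distance gap to suppress chatter.

# The synthetic enzyme and study conditions

`make_toy_enzyme()` builds a two-pocket "clamshell" enzyme: a rigid shared
CORE (pocket floors, inner ridges, outer walls, end walls) and two mobile
caps — NMP closing over a 5-bead AMP-like ligand, LID over a 7-bead
ATP-like one. The open conformer rotates each cap 60 degrees about a hinge
axis running along its outer wall row. Two geometric features carry the
mechanism:

* every protein–ligand clearance in the closed pocket is near or above the
  5 Å excluded-volume diameter, so the native complex is strain-free, while
  a flipped (non-native) pose collides with the cap lips and destabilises
  only the closed state;
* each cap carries two "lip" bead rows sealing the side channels of the
  closed pocket. A mis-bound ligand therefore cannot slip out sideways
  while the enzyme is closed — confinement is real — and the lips swing
  away with the cap, so opening genuinely frees the ligand. Lip positions
  are chosen so their distances to all fixed beads grow monotonically
  during the swing (no mid-swing steric squeeze).

The study conditions, frozen in `toy_study_params()`, are: `eps_pp = 1.0`
kcal/mol, `Delta = 4` kcal/mol per interface, and per-interface `deltaV`
(-6.0 for LID-CORE, -7.1 for NMP-CORE) calibrated with
`calibrate_basin_offset()` (bisection against short apo runs) so the apo
enzyme is genuinely bistable with a joint closed population near the
experimentally known 0.3 (measured 0.25-0.37 across seeds at the
calibration sampling). Problem sizes in the shipped analyses (typically
8-20 trajectories of 1-2.5 x 10^5 steps per condition) are chosen so each
study runs in minutes on one core while still separating the reported
effects beyond their bootstrap intervals.

Three protocol details of the binding study deserve explicit statement.
Encounter complexes place each ligand near its groove in a fully random
orientation. The closed-locked control (`C`) follows the published recipe:
it continues each free run from its first arrival at the closed structure
(protein RMSD below 2 Å) with a conformational lock applied, excludes
snapshots whose substrate has drifted out of the binding area, and counts
parents that never close as right-censored — its clock runs from the
shared encounter start, so the two variants answer the same question
("how long until native binding?") with and without the freedom to reopen.
Binding success uses the fraction-of-native-contacts rule
(`Q >= 0.7` for both ligands simultaneously), which in this geometry can
only be met with the caps closed over correctly oriented ligands; the
ligand is deliberately long enough that a head-to-tail reversed pose
scores well below the threshold. The free-energy study profiles one
domain's opening with the other substrate kept native, mirroring the
published setup (non-native AMP, native ATP), and is run at low
`eps_nnat` where the steric destabilisation dominates: at larger
ruggedness the non-native wells themselves stabilise the closed cage and
the landscape inversion weakens — the same non-monotonicity seen in the
opening kinetics.

What the toy system does *not* emulate: a real fold's sequence and packing,
funnel-shaped folding energetics (domains here are permanently folded),
solvent and electrostatics, and the all-atom geometry of nucleotide
binding. Passing the trend studies therefore demonstrates the *mechanism* —
conformational cycling rescues mis-bound substrates on a rugged landscape —
not a quantitative prediction for AdK. Crystal-structure input through
`load_reference_pair()` uses exactly the same machinery, so the same
studies can be repeated on a real open/closed pair when structures are
available.

# Degenerate inputs and tie-breaks

Empty contact maps are permitted (separated molecules); `Q` on an empty
contact list is an error (undefined). Kabsch superposition rejects
collinear subsets. `xi` requires distinct references. The double-basin
weights fall back to (1/2, 1/2) at the exact degeneracy
`V1 = V2, Delta = 0`. Dihedral terms skip configurations that reach exact
collinearity at evaluation time.

# Known limitations

* The calibration target (apo closed population) is estimated from finite
  unbiased runs whose transition counts are modest; the calibrated
  `deltaV` carries a few-tenths kcal/mol uncertainty, and populations
  respond steeply to it.
* The exponential first-passage model is an approximation for the
  non-native conditions, where escape may be multi-step.
* The cycling demand grows with ruggedness for the AMP/NMP side but not
  for the ATP/LID side of this toy: the seven-bead ligand's non-native
  wells guide it into its groove quickly, so the LID cap cycles less at
  high `eps_nnat`. The NMP side is therefore the quantitative carrier of
  the cycling trend.
* The free-energy landscape inversion under a mis-bound ligand is probed
  at low `eps_nnat`; at 0.5 the non-native attraction to the closed cage
  partially offsets the steric destabilisation.
* With unit masses the absolute time unit `tau` has no physical calibration;
  all kinetic comparisons are made within the model.
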