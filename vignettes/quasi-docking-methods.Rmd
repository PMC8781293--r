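---
title: "Quasi-docking: models, procedure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-docking: models, procedure, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasidock)
```

## The problem and the two-step procedure

Most docking programs rest on the *docking paradigm*: the bound pose of a
ligand in a rigid receptor coincides with the global minimum of the energy of
the complex. Testing that paradigm under a quantum-chemical energy is not
directly tractable — the global optimization would need millions of
quantum-chemical evaluations over a surface with a great many local minima.
Quasi-docking approximates quantum docking in two steps:

1. **Search.** Enumerate a wide spectrum of low-energy minima of the complex
   under a *fast* stage-1 energy model. Random starts are produced by drawing
   a uniform rigid-body placement of the ligand inside a binding-site sphere
   (uniform rotation via unit quaternions; the geometric center uniform over
   the ball) together with uniform torsion angles, rejecting clashing poses,
   and locally minimizing the energy with L-BFGS over *all* ligand Cartesian
   coordinates. Unique minima — uniqueness decided by heavy-atom RMSD — are
   kept in a fixed-capacity pool ordered by energy.
2. **Re-rank.** Recompute the energy of every pool minimum *single-point*
   (coordinates untouched) under a slower stage-2 model — a semiempirical
   quantum-chemical method with an implicit solvent, reached through a
   MOPAC-dialect file interface, or a bundled smooth surrogate — and re-rank
   ascending. The rank-1 minimum is the declared global minimum (GM); its
   pose is the predicted binding mode.

The working assumption is that the stage-2 global minimum's pose is *among*
the stage-1 minima: stage 1 proposes, stage 2 disposes.

Positioning quality is reported through the Index Near Native (INN): minima
are ranked by stage-2 energy, and INN is the rank of the lowest-energy
minimum whose heavy-atom RMSD to the crystallographic pose is below 2 Å
(strictly below; the bound is part of the criterion's definition). INN = 1
means the docking paradigm held. The RMSD convention is the docking one:
poses share the receptor frame and are never superposed first.

## Energy models

Both stages plug into one contract: `evaluate(receptor, ligand, pose)` in
kcal/mol, deterministic for identical inputs, with an *optional* analytic
gradient (`gradient()`), falling back to central finite differences. This
lets single-point-only backends (external quantum-chemistry programs) and
differentiable backends (force fields, the bundled toy models) share the
search and protocol code. Energies stay in kcal/mol throughout — both
force-field energies and semiempirical heats of formation natively use that
unit — so no conversion layer exists.

The package does not ship a molecular-mechanics force field. Production
stage-1 backends attach behind the model contract; everything the package
itself demonstrates and tests runs on bundled smooth models built from four
term types with analytic gradients:

* **pairwise springs** `k (d - d0)^2` pinning a toy ligand's internal
  geometry (bonds, angles) while leaving chosen degrees of freedom free;
* a **quartic double well in an atom-pair distance**, carving a two-well
  torsional profile (gauche/anti) through the 1–4 distance, with a linear
  tilt making the wells inequivalent;
* **full-pose attraction wells**: each well contributes
  `-depth / (1 + D^2/lambda^2)` where `D^2` is the summed squared deviation
  of the whole pose from a target pose. The slowly decaying tail keeps the
  gradient meaningful everywhere in the site, so every start is downhill
  from some well and the model's minima set is exactly the designed well
  set — the property that makes the toy landscapes enumerable;
* **soft Lennard-Jones + damped Coulomb** pairs between ligand and receptor
  atoms (`eps (u^4 - 2u^2)` with `u = sigma^2/(d^2 + delta)`, plus
  `332.0636 q_i q_j / sqrt(d^2 + delta)`), the stage-2 surrogate.

Since the receptor is rigid, any intra-receptor energy is an additive
constant; models may report it through `receptor_energy()` (used as the
unbound-protein term of the enthalpy protocol) and otherwise leave it at 0.
Reported complex energies therefore carry a model-dependent constant offset,
which cancels in all differences the package reports.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `site_radius` | 8 Å | sphere confining the ligand's geometric center |
| `clash_scale` | 0.5 | clash when `d <` 0.5 × summed Bondi vdW radii |
| `grad_tol` | 1e-3 kcal/mol/Å | L-BFGS projected-gradient stop |
| `capacity` | 8192 | pool size; raise it freely for hard cases |
| `uniqueness_rmsd` | 0.5 Å | heavy-atom RMSD merging two minima |
| `eps` (COSMO) | 78.4 | water dielectric passed to the external program |
| `cutoff` (INN) | 2 Å | near-native threshold, strict inequality |

Where the procedure's published description leaves a numeric choice open,
the default above is this package's declared choice, not an external fact:

* **Clash threshold.** "Clash" is quantified as distance below 0.5 × the sum
  of Bondi van der Waals radii, ligand–receptor and ligand–ligand alike,
  with 1–2 and 1–3 ligand pairs exempt (bonded geometry is legitimately
  short). The factor is permissive by design: start poses only need to be
  good enough for L-BFGS to resolve soft overlaps.
* **Optimizer stop.** 1e-3 kcal/mol/Å on the gradient infinity norm keeps
  duplicate-minimum RMSD scatter far below the pool's 0.5 Å uniqueness
  threshold, so basins are split by geometry, not optimizer noise.
  Non-converged results remain eligible for the pool but are flagged.
* **Pool uniqueness.** 0.5 Å is well under the 2 Å success criterion and
  well above optimizer jitter. Pool RMSD uses heavy atoms under the
  *identity* atom mapping; symmetry corrections are an analysis-time concept
  (applying them inside the pool would change which minima are retained).
* **Duplicate resolution.** A candidate landing within the uniqueness radius
  of a stored record replaces it iff its energy is lower, so each basin is
  represented by its best-converged point.
* **Stage-2 ties.** Equal rescored energies (possible with truncated printed
  precision) break by stage-1 energy, then insertion order — deterministic
  and documented.
* **Torsion conventions.** A rotatable torsion is a single-order, acyclic
  bond with non-terminal endpoints. Rotation moves the side of the bond with
  fewer atoms (tie: the side holding the lower minimum atom index). Torsions
  are randomized before rigid placement; for a uniform sampler the order is
  immaterial, and this one is fixed for reproducibility.

## The saddle problem

Quasi-Newton minimizers are attracted to *any* stationary point whose
neighborhood they enter, and a tight gradient tolerance makes stopping on a
flat saddle (e.g. a torsional barrier top, or a torque-free orientation of a
pose inside an attraction well) a real event rather than a measure-zero
curiosity. Two defenses are built in:

* every converged optimization is re-run from a small deterministic kick
  (`saddle_kick`, default 0.02 Å, a fixed sinusoidal pattern); the kicked
  result is adopted only when strictly lower. True minima shrug the kick
  off, so results at minima — including the exact-fixed-point case — are
  unchanged;
* the toy-landscape oracle additionally rejects any enumerated candidate
  that a perturbed restart escapes, and its fixed orientation grid uses
  deliberately skew axes and angles, never an exact symmetry rotation of the
  ligand: a start placed exactly on a well's symmetry axis would sit on a
  saddle's invariant manifold and "converge" onto it.

## Binding enthalpy

The binding enthalpy estimate is the difference of global-minimum energies

```
dH_bind = E1(PL) - E1(P) - E1(L)
```

with all three terms from the same stage-2 method/solvent combination
(mixing methods across the three terms is rejected). `E1(PL)` relaxes the
complex from the GM pose by varying all ligand Cartesians under the vacuum
stage-2 model, then evaluates the solvent model single-point at the relaxed
geometry. `E1(P)` is the unbound receptor in its fixed docking conformation
(no relaxation). `E1(L)` relaxes each unbound-ligand conformer of a stage-1
conformer pool under the vacuum model, evaluates the solvent model
single-point at each, and takes the minimum. Entropic and vibrational
contributions, and all higher minima, are deliberately neglected: the
estimate is an enthalpy of the deepest basin, which is also why it is only
computed for complexes whose positioning succeeded. The self-consistency
anchor (tested): with stage-2 equal to stage-1 and a single conformer, the
formula collapses to the directly computed interaction energy to 1e-8
kcal/mol.

The correlation between measured and calculated enthalpies over the packaged
benchmark is the sample Pearson coefficient over complete pairs. Pearson is
a documented choice: recomputing both packaged columns gives 0.74 and 0.40
under Pearson (matching the published summary values), while rank
correlation does not, which settles what the published coefficient was.

## Synthetic complexes: what they emulate, and what not

`build_toy_complex()` makes a pocket — a ring of carbon pseudo-atoms plus
one charged "hotspot" oxygen — and a small rigid ligand whose stage-1
landscape is a designed set of K attraction wells with distinct depths
(circle layout up to K = 6, Fibonacci-sphere layout beyond, keeping wells
separated relative to their width so none merges). The complete minima list
is enumerated by brute force: a deterministic translation grid crossed with
a fixed skew orientation set, L-BFGS refinement, RMSD deduplication, saddle
rejection. That oracle is what the stochastic pipeline is tested against:
a search with 50·K starts must recover the entire oracle set.

The stage-2 surrogate's charges are arranged so its global minimum sits in a
*different* well than stage 1's, so re-ranking genuinely permutes the order
and the INN machinery is exercised for real: evaluated against the stage-1
GM basin as "native", the paradigm fails after rescoring; against the
surrogate-GM basin, it holds. A symmetric-ligand variant (a square ring)
expands each designed well over the ligand's graph automorphisms, producing
equal-energy minima groups that are distinct under the identity mapping but
identical after symmetry correction — the analysis-time analogue of a ligand
crystallized in two symmetry-equivalent binding modes.

What the toys do *not* emulate: force-field physics (electrostatics,
dispersion, desolvation), protein flexibility, rugged funnels with
thousands of minima, protonation ambiguity. Passing the toy-scale tests
demonstrates the correctness of the search/pool/re-rank/evaluate machinery,
not the chemical accuracy of any energy model; on real complexes accuracy is
the backend's affair.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are chosen for a
single-CPU desk run: toy complexes with K ∈ {2, 5, 10} wells, 20 seeded
searches of 50·K starts each for recovery rates, a 10,000-candidate stream
against the brute-force pool oracle, 100-start runs for byte-identical
determinism checks. The pool TSV is written with fixed 8-decimal formatting
so identical runs are byte-identical on disk; per-start RNG substreams are
derived from (master seed, start index), which makes the pose stream — and
therefore the pool — independent of how starts are distributed over
workers.

Degenerate inputs are rejected early: empty ligands, non-connected bond
graphs, ring bonds declared as torsions, unknown elements in the van der
Waals table, non-finite energies at a start pose. A start whose clash
rejection exhausts its retry budget signals an overfilled site rather than
looping forever; an optimization hitting a non-finite energy mid-line-search
discards that start with a logged reason and the run continues.

## Known limitations

* No external semiempirical program ships with the package; the MOPAC-dialect
  writer/parser and the canned-output fixtures define and test the file
  contract, but live integration needs the program installed.
* The exact keyword set beyond `1SCF MOZYME CHARGE EPS` that a production
  run would pin (SCF convergence criteria, cutoffs) is configuration, not
  code.
* The symmetry-corrected RMSD enumerates graph automorphisms (VF2, capped at
  10,000); pathological ligands exceed the cap and require an explicit
  mapping. Receptor-side symmetry (homodimers with two equivalent sites) is
  handled by supplying alternative native reference poses, not by receptor
  graph analysis.
* The pool's arrival-order invariance holds up to basin-representative
  choice; with capacity far below the basin count and large within-basin
  energy spread, eviction can make late-arriving basins transiently
  rankable. The saturation diagnostic is the intended guard: runs should
  continue until the spectrum stops improving.
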