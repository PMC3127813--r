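---
title: "Per-residue contact profiling of docking ensembles and trajectories"
author: "contactprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue contact profiling of docking ensembles and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactprof)
```

## The problem

When a flexible, branched ligand — here the motivating system is a
partially glycosylated generation-3.5 PAMAM dendrimer binding the
lipid-binding co-receptor MD-2 — is docked rigidly against a receptor,
no single pose is trustworthy. What is informative is the *ensemble*:
hundreds of retained low-energy solutions, summarised residue by
residue. `contactprof` implements that summary, the interaction
fingerprint, and the statistics built on it:

1. **Contact profile.** For each receptor residue, the number of
   (ligand atom, receptor atom) pairs closer than a cutoff (default
   3 Å, strict `<`), summed over all poses of an ensemble
   (`count_contacts()`, `ensemble_profile()`).
2. **Energy weighting.** Each pose's counts multiplied by the
   magnitude of its docking energy, so strong solutions dominate
   (`energy_weighted_profile()`).
3. **Differential profile.** Elementwise subtraction of a
   negative-control ligand's profile (an unmodified dendrimer that is
   biologically inactive), isolating the binding attributable to the
   modified moieties (`differential_profile()`).
4. **Ranking and enrichment.** The top-k residues
   (`top_residues()`) and the fraction of (positive) profile mass
   inside a residue window of interest — for MD-2, residues 84–127
   lining the entrance of its hydrophobic pocket
   (`window_enrichment()`).
5. **Exposure vs. selectivity.** Per-residue Shrake–Rupley
   solvent-accessible surface area (`shrake_rupley()`), contrasted
   with contact counts: the most exposed residues need not be the most
   contacted ones, which is evidence of selectivity.
6. **Trajectory statistics.** For a molecular-dynamics trajectory of
   the complex: per-frame close contacts, per-moiety contacts,
   geometric hydrogen-bond counts, the number of "engaged" moiety
   units (e.g. how many glucosamines touch the receptor), and the
   buried interface area per frame (`contact_series()`,
   `hydrogen_bonds()`, `contact_area()`).

## Counting semantics

"Number of interactions" is ambiguous between atom pairs and distinct
ligand atoms. The package counts **pairs** by default (each ligand
atom / receptor atom pair under the cutoff counts once) because pair
counts are the stricter superset and produce fewer ties; the
distinct-ligand-atom reading is available via `count_mode = "atom"`.
The cutoff comparison is strict (`<`), and the cutoff itself is a free
parameter everywhere — analyses at 3 Å and at 6 Å are both legitimate.

A sub-2 Å "close contact" criterion cannot be an atom-centre distance
(centres that close would be covalent). The package therefore supports
two distance semantics: `"center"` (atom-centre Euclidean distance)
and `"surface"` (centre distance minus both van der Waals radii, i.e.
the vdW gap). The `"auto"` mode selects `surface` for cutoffs below
2 Å and announces its choice; every profile records the mode in its
metadata. Neither semantics is asserted to be the original analysis
tool's — both are provided.

Distances are found with a cell-list (spatial grid) neighbour search:
atoms are binned into cubic cells at least as wide as the effective
cutoff, and only the 27 surrounding cells are examined per query atom.
The test suite pins this implementation against an independent
all-pairs brute-force double loop on randomised instances, exactly.

## SASA and buried interface area

The solvent-accessible surface area uses Shrake–Rupley sampling with a
**deterministic golden-spiral point set** (default 960 points per
atom, probe 1.4 Å, Bondi radii; unknown elements get 1.7 Å with a
warning). The deterministic point set makes results bit-reproducible
and lets closed-form oracles (isolated sphere, two-sphere
spherical-cap overlap) pin the accuracy: within 1% for an isolated
sphere and 2% for overlapping spheres at 960 points.

The interface ("contact") area between two parts of a complex is the
standard SASA-difference definition:

$$A_{buried} = \tfrac{1}{2}\left(SASA_A + SASA_B - SASA_{AB}\right)$$

which is symmetric, non-negative, parameter-light and oracle-checkable
against the analytic two-sphere buried caps. This deliberately
diverges from vertex-proximity contact-area measures used by some
visualisation tools (cut-off based); reproducing those numbers is a
non-goal. Because three SASA evaluations per frame are the costly step
of the trajectory pipeline, the per-frame area series is computed on a
frame stride (default every 10th frame, 240 sphere points), mirroring
the common practice of analysing selected frames; both knobs are
arguments.

## Hydrogen-bond detection

The geometric criteria are configurable (`hbond_criteria()`): maximum
donor–acceptor heavy-atom distance 3.5 Å and minimum donor–H–acceptor
angle 120° by default — standard values, chosen here because the
motivating analysis does not state its criteria. Docking poses often
carry no hydrogens; in that case the detector falls back to a
heavy-atom distance-only mode (3.5 Å) and says so. Requesting the
angle criterion without hydrogens is an error that names the fallback.

## The synthetic-data generators

No coordinates from the motivating study are redistributable at desk
scale, so every pipeline stage is exercised on seeded synthetic systems
with planted ground truth. The generators emulate the *statistical
shape* of the real problem, not its chemistry:

* `make_receptor()` — 160 coarse residues (4 pseudo-atoms each, real
  element symbols) at uniform surface density on a 25 Å sphere zone
  whose empty 12° polar cap is the pocket mouth; the 44 residues
  ringing the cap rim are the entrance window and carry residue
  numbers 84–127. The lattice starts as a golden-angle spiral and is
  relaxed by tangential repulsion: a plain spiral clusters points near
  the zone ends, which would give those residues systematically more
  contact opportunity and bias the null enrichment away from the
  uniform value 44/160.
* `make_ligand()` — a star-topology pseudo-dendrimer: 64 carboxylate
  branch terminals (3 atoms each) at seeded radii 7.5–13 Å — the
  spread makes the surface bumpy, so a touching pose contacts the
  receptor through a few protruding tips rather than a smooth shell —
  and 8 glucosamine units (8 atoms each, nitrogen donors and oxygen
  acceptors) on 14.5 Å branches, the longest, as conjugated surface
  groups are. Setting `n_glucosamine_units = 0` yields the unmodified
  negative-control ligand.
* `make_pose_ensemble()` — rigid placements with collision-aware
  depth (a pose may not interpenetrate the receptor). *Background*
  poses touch a uniformly chosen receptor residue through a random
  carboxylate tip, with the approach depth standardised to a small
  per-pose contact target (2–4 anchor pairs): the same non-specific
  process for test and control ligand, so backgrounds cancel in the
  differential and the background contact mass is uniform per residue
  — the property behind the null calibration. *Planted* poses dock a
  glucosamine unit onto entrance-window residues (a shuffled cycling
  permutation, so the planted truth covers the rim evenly, as docking
  clusters along a binding site do), approaching over the pocket
  mouth so the ligand body overhangs the opening. The planted depth
  is searched on a fixed grid until the pose makes at least
  `enrichment_ratio` (default 5) times the mean background
  anchor-pair count with its anchor residue — the per-residue-rate
  reading of "planted contacts at *r* times the background rate" —
  and is capped by geometry when the grid is exhausted. Planted poses
  draw more favourable energies (Normal(−8, 1) vs Normal(−4, 1),
  arbitrary docking-score units).
* `make_trajectory()` — an approach trajectory of the complex with a
  non-increasing gap schedule and an exact engaged-unit schedule: in
  each frame the first *k(t)* glucosamine units are pinned at a fixed
  sub-cutoff vdW gap (0.4 Å) against fixed window sites and the rest
  are kept clear (≥ 6 Å), so with `jitter = 0` the engaged-unit count
  equals the schedule in every frame. The default schedule steps from
  3 to 4 engaged units at half time, emulating a binding
  rearrangement.
* `make_hbond_frame()` — well-separated donor–H–acceptor triplets:
  ideal (collinear, 2.9 Å), angle-violating decoys (60° at H) and
  distance decoys, for exact-recovery tests of the detector.

All generators draw from a single RNG stream seeded from the
configuration (`generator_config()`), so outputs are byte-identical
across runs; ground truth is written as sidecar TSVs rather than
reaching into generator internals.

### What the generators do and do not emulate

They reproduce: ensemble bookkeeping (e.g. 20 solutions × 20
conformations = 400 poses per ligand, 800 processed solutions),
planted interface structure with a controllable enrichment ratio and
fraction, energy ordering of planted vs background solutions, moiety
labelling with hydrogen-bond roles, and scripted trajectory behaviour.
They do **not** reproduce covalent geometry, sterically realistic
dendrimer conformations, force-field energetics, or the actual
MD-2/dendrimer coordinates — so passing tests demonstrate the
correctness and sensitivity of the *analysis*, not any biological
conclusion about the real system.

## Study-scale defaults and problem sizes

Defaults mirror the motivating study's bookkeeping: a 160-residue
receptor, window 84–127, 8 glucosamine units, 64 carboxylates, 3 Å
profile cutoff, 1.3 Å trajectory close-contact cutoff, 4.8 ps frame
interval. Statistical checks in the test-suite run 20 seeds × 100
poses per ensemble (planted fraction 0.5, enrichment ratio 5), and
trajectory checks use 20–40 frames; these sizes give stable means
(observed seed-to-seed standard deviation of the null enrichment is
about 0.05) while keeping a full run of the suite in minutes.

## Numerical choices and degenerate inputs

* Coordinates round-trip through fixed-width PDB at the format's
  3-decimal precision; author residue numbering and insertion codes
  are preserved verbatim and are the coordinate system of all
  profiles. Altlocs resolve to the first conformer; hydrogens are
  kept if present and never added.
* Ties in `top_residues()` break by ascending residue number, then
  chain — fully deterministic.
* `window_enrichment()` of a differential uses only the positive part
  of each value; a profile with zero total mass is an explicit error
  ("empty profile"), and the pipeline reports an undefined enrichment
  (`NA`) for an all-zero differential rather than failing.
* Profiles refuse to combine across mismatched receptors, cutoffs,
  modes or weightings, naming the first mismatch.
* The PDB writer enforces the 99 999-atom format limit; multi-model
  readers verify a consistent atom count per MODEL and name the
  offending model.

## Limitations

* The pair/atom counting ambiguity and the centre/surface distance
  ambiguity of sub-2 Å contacts are resolved by configuration, not by
  assertion; comparisons against analyses made with other tools must
  match modes explicitly.
* The SASA-difference contact area is not numerically comparable to
  vertex-counting contact areas from visualisation software.
* Background-pose uniformity holds in expectation per residue; with
  few poses the per-seed null enrichment is noisy (hence the
  multi-seed calibration checks).
* The generators make no attempt at physical realism beyond what the
  analyses consume: coordinates, elements, labels and energies.
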