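# contactprof

Per-residue contact profiling of protein–ligand docking pose ensembles
and molecular-dynamics trajectories.

## The problem

Rigid docking of a large, flexible ligand — the motivating system is a
partially glycosylated generation-3.5 PAMAM dendrimer binding MD-2,
the 160-residue lipid-binding co-receptor of TLR4 — produces hundreds
of retained solutions, none individually trustworthy. The informative
object is the *per-residue interaction fingerprint* aggregated over
the ensemble, compared against a biologically inactive control ligand.
`contactprof` implements that analysis end to end:

- **Contact profiles** — for every receptor residue *r*, the number
  of (ligand atom, receptor atom) pairs with distance `< cutoff`
  (default 3 Å), summed over all poses; optional restriction to a
  labelled moiety (e.g. the ligand's glucosamine units).
- **Energy-weighted profiles** — per-pose counts scaled by |E|, so
  favourable solutions dominate:
  `track[r] = Σ_poses count_pose[r] · |E_pose|`.
- **Differential profiles** — `test − control`, isolating
  moiety-attributable binding.
- **Ranking and window enrichment** — top-k residues and the fraction
  of (positive) differential mass inside a residue window of interest,
  e.g. residues 84–127 lining the entrance of MD-2's hydrophobic
  pocket.
- **Shrake–Rupley SASA** (deterministic golden-spiral point set) and
  the buried interface area
  `(SASA_A + SASA_B − SASA_AB) / 2` per trajectory frame.
- **Trajectory series** — per-frame close contacts (centre or
  vdW-gap distance semantics), per-moiety contacts, geometric
  hydrogen bonds (3.5 Å / 120° with a heavy-atom fallback), and
  engaged moiety units (units with ≥ 1 atom in contact).
- **Seeded synthetic generators** — receptor with a designated pocket
  entrance, dendrimer-like labelled ligand, pose ensembles with a
  planted binding interface and known ground truth, scripted approach
  trajectories — so the whole pipeline is testable without any
  external data.

## Worked example

Generate a planted scenario and recover the interface:

```r
library(contactprof)

cfg <- generator_config(seed = 42, n_poses = 100)   # planted fraction 0.5
receptor <- make_receptor(cfg)
lig  <- make_ligand(cfg)                            # 8 glucosamines, 64 carboxylates
glyc <- make_pose_ensemble(receptor, lig$structure, lig$labeling, cfg)$ensemble

cfg0 <- generator_config(seed = 42, n_poses = 100, planted_fraction = 0,
                         n_glucosamine_units = 0)   # negative control
lig0  <- make_ligand(cfg0)
unmod <- make_pose_ensemble(receptor, lig0$structure, lig0$labeling, cfg0)$ensemble

prof_glyc  <- ensemble_profile(glyc,  cutoff = 3, contact_mode = "center")
prof_unmod <- ensemble_profile(unmod, cutoff = 3, contact_mode = "center")
diff <- differential_profile(prof_glyc, prof_unmod)
diff
#> ResidueProfile 'glycosylated - unmodified' over 160 residues of 'synthetic_receptor_seed42'
#>   cutoff 3 A (center), pair counts, weighting none, 200 pose(s), differential
#>   total 5018, nonzero residues 128

top_residues(diff, 5)
#>        key chain resno resn value
#> 1 A:85:ARG     A    85  ARG   237
#> 2 A:84:TYR     A    84  TYR   229
#> 3 A:91:LYS     A    91  LYS   220
#> 4 A:95:GLY     A    95  GLY   211
#> 5 A:89:ALA     A    89  ALA   197

window_enrichment(diff, c(84, 127))
#> [1] 0.9315...
```

The five highest-ranked residues all fall inside the planted entrance
window (84–127), and 93% of the positive differential mass lies in the
window — the generator planted half of the glycosylated ensemble's
poses there, and the background contacts of the two ensembles cancel.
Receptor exposure for the selectivity comparison:

```r
sasa <- shrake_rupley(receptor)
sasa
#> SasaResult: 640 atoms, total 21945.1 A^2 (probe 1.4 A, 960 points, bondi radii)
```

The same analysis runs from the shell over files
(`exec/contactprof`, installed with the package):

```sh
contactprof simulate --seed 42 --n-poses 100 --out scenario/
contactprof profile  --config scenario/run.yaml
contactprof traj     --config scenario/run.yaml
contactprof sasa     --receptor scenario/receptor.pdb --out sasa.tsv
```

`profile` writes raw / energy-weighted / differential profile TSVs,
the per-residue SASA and selectivity tables, the top-k ranking and a
manifest with checksums; `traj` writes the per-frame contact /
hydrogen-bond / engaged-unit series and the buried contact-area
series.

## The methods vignette

`vignettes/contact-profiling.Rmd` documents the counting semantics
(pair vs distinct-atom, centre vs vdW-gap distance), the SASA and
interface-area definitions, the hydrogen-bond criteria, the design of
the synthetic generators (what they emulate and what they deliberately
do not), numerical choices, and limitations.
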