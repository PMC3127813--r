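Package: contactprof
Title: Per-Residue Contact Profiling of Docking Pose Ensembles and
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interaction fingerprinting of protein-ligand
    docking pose ensembles and molecular dynamics trajectories:
    per-residue contact counting under a distance cutoff, energy-weighted
    and differential (test minus negative-control) interaction profiles,
    residue ranking and region-of-interest enrichment, Shrake-Rupley
    solvent-accessible surface area and buried interface area,
    time-resolved contact, hydrogen-bond and engaged-moiety-unit series,
    plus seeded synthetic generators (receptor with a designated pocket
    entrance, dendrimer-like branched ligand, pose ensembles with a
    planted binding interface, approach trajectories) for end-to-end
    benchmarking with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
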