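Package: anionpi
Title: Anion-Pi Contact Geometry and Ensemble Analysis for RNA Tetraloops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric and statistical analysis of phosphate-guanine
    anion-pi interactions in RNA GNRA-family tetraloops. Provides the
    (distance, angle) anion-pi descriptor with ring-plane decomposition,
    tetraloop detection in PDB/mmCIF structures, ensemble profiling
    (superposed RMSD with sliding-window statistics, per-residue side-chain
    RMSF, distance-angle distributions, snapshot selection, native-contact
    conservation, ion/water occupancy grids), a binned dimensionless
    torsional-entropy statistic with pseudo-counts, a synthetic-structure
    generator for validation (idealized guanine rings, parameterized
    phosphate placements, two-state conformational ensembles, circular
    dihedral samples), and export of capped base/phosphate model fragments
    for external quantum-chemistry engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
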