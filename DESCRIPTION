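Package: allomap
Title: Allosteric Coupling Maps from Backbone Electrostatics and NMR Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map allosteric coupling in proteins from molecular
    dynamics trajectories and solution NMR data. Computes Kabsch-Sander
    backbone hydrogen-bond electrostatic energies, per-residue
    secondary-structure propensities, root-mean-square fluctuations, and
    electrostatic eigenvector centrality (EEC) networks from backbone
    coordinate ensembles; quantifies chemical-shift perturbations, line
    broadening, and R1/R2/heteronuclear-NOE spin relaxation from assigned
    peak lists and decay tables; and calls mutant-versus-wild-type hotspots
    with trimmed-mean/sigma significance thresholds. A synthetic-data
    module generates trajectories, peak lists, and relaxation decays with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
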