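Package: fibrilTools
Title: Construction and Trajectory Analysis of Three-Fold-Symmetric Amyloid Fibril Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing structural models of amyloid-beta
    fibrils with three-fold symmetry. Provides layer replication from a template
    layer, N-terminal truncation with acetyl capping, solvated-system composition
    accounting with counter-ion neutralisation, and the periodic z-box adjustment
    used to set up infinite fibrils. Trajectory analyses include the mean
    inter-filament axis angle, the Met35-Met35 central-pore dimension, backbone
    RMSD/RMSF after rigid-body superposition, radius of gyration, residue-pair
    distances, 4 Angstrom atom-pair contact statistics (contact-frequency maps,
    per-chain kymographs, inter-filament contact series), and a contact-based
    classifier of fibril topology (triple-symmetric, 2+1, dissociated). A
    deterministic synthetic fibril and rigid-body trajectory generator stands in
    for molecular-dynamics output so that every analysis is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
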