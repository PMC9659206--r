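Package: ltqdyn
Title: Modelling and Trajectory Analysis of LTQ-Containing Amine Oxidase Active Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to remodel a precursor lysyl oxidase-like (LOXL) structure into a
    mature, lysine tyrosylquinone (LTQ)-containing model and to characterise the result.
    Provides PDB and XYZ trajectory input/output with atom selection, a vector-geometry
    kernel (distances, angles, dihedrals, least-squares superposition, RMSD), backbone
    dihedral transplantation with internal-coordinate rebuilding, cofactor construction
    by molecular-graph patching, metal swapping and coordination-water placement,
    metal-site analysis (coordination-sphere detection, Addison tau, Jahn-Teller axis,
    rotamer classification, pi-stacking and van der Waals contacts), trajectory
    statistics (fitted RMSD series, RMSF, B-factors, C-alpha covariance PCA,
    displacement fields, tau and rotamer time series), and deterministic synthetic-data
    generators for testing every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
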