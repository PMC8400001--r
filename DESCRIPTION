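Package: catnap
Title: Contact Occupancy, Enzyme Assay and Brain Injury Analytics for
    Protein Nanoparticle Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing analytics for hydrophobic ion pairing (HIP)
    nanomedicine studies of catalase and serum albumin. Computes
    per-residue ligand-contact occupancy, residue-class fraction profiles
    and Kabsch-superposed backbone RMSD from molecular dynamics
    trajectories (multi-model PDB), Shrake-Rupley solvent-accessible
    surface composition, Beers-Sizer catalase activity from kinetic A240
    traces, BCA protein quantification, binding efficiency, specific
    activity and deactivation, protease-protection retention,
    ion-pairing stoichiometry inventories, and brain-injury endpoints
    (hemisphere area loss, 0-4 ordinal gross-injury scoring, Wilcoxon-
    Mann-Whitney and Welch tests). Ships deterministic synthetic-data
    generators with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
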