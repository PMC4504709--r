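Package: IFDimerTools
Title: Structural Analysis of Intermediate Filament Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry and contact analysis for intermediate filament (IF)
    protein dimers such as the epithelial keratin K1/K10 heterodimer.
    Computes per-residue coiled-coil profiles (central axis, local
    superhelical radius, rotation angle, local pitch, handedness),
    subdomain major axes and hinge angles, head/tail globule placement
    metrics (axial displacement and radial orientation with Category
    I/II/III classification), shape metrics (radius of gyration,
    end-to-end distance, principal extents), C-alpha contact maps with
    ensemble contact probabilities, typed side-chain contact censuses,
    heptad-register ideal contact counts and hydrogen-bond tallies.
    Includes a model-building layer that enumerates hairpin-fold starting
    configurations of the disordered head/tail domains and a synthetic
    structure generator (Crick coiled-coils, ideal alpha-helices, compact
    random-walk globules, jittered frame ensembles) providing exact
    geometric ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'IFDimerTools-package.R'
    'utils-geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structure_io.R'
    'synthetic_data.R'
    'coil_geometry.R'
    'domain_geometry.R'
    'contacts.R'
    'heptad.R'
    'model_builder.R'
    'sequence_metrics.R'
    'pipeline.R'
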