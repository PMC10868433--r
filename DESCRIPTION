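Package: imembrane
Title: Implicit Membrane Geometries for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implicit representation of lipid membranes around protein
    structures as smooth hydration fields. Provides transition functions for
    flat bilayers (slab), ellipsoidal membrane mimetics (micelles and
    bicelles), spherical bilayers (vesicles, modelling curvature) and double
    membranes, together with an aqueous-pore field that composes with every
    geometry. Includes analytic gradients, a geometry-dependent burial free
    energy, residue environment classification, geometry-parameter estimation
    against membrane-spanning annotations, decoy-discrimination metrics
    (enrichment, Pnear) and design-benchmark statistics, PDB and spanfile
    input/output with B-factor annotation for visualisation, and synthetic
    structure generators so the whole stack is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'transition.R'
    'hydration.R'
    'structure-io.R'
    'spanfile.R'
    'scoring.R'
    'param-tools.R'
    'metrics.R'
    'synthetic.R'
    'config.R'
    'cli.R'
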