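Package: abtap
Title: Structure-Based Developability Profiling of Antibody Fv Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes structure-based developability metrics for
    IMGT-numbered antibody Fv models: total CDR length, patches of
    surface hydrophobicity (Kyte-Doolittle), patches of surface positive
    and negative charge, and the structural Fv charge symmetry
    parameter. Solvent accessibility is computed with a deterministic
    Shrake-Rupley implementation; patch scores are decomposed into
    pairwise residue contributions. Percentile flagging thresholds are
    fitted from a reference cohort, with confidence filtering on
    predicted-error annotations, repeat-run ensemble consensus, cohort
    comparisons (flag rates, CDR-length statistics, gene-usage
    enrichment), and framework-aligned per-region backbone RMSD. A
    deterministic synthetic-structure generator makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abtap-package.R'
    'cli.R'
    'cohort.R'
    'config.R'
    'fixtures.R'
    'flagging.R'
    'metrics.R'
    'pdb-io.R'
    'regions.R'
    'structcompare.R'
    'surface.R'
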