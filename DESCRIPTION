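Package: covkin
Title: Potency, Promiscuity and Structural Triage of Covalent and
    Allosteric Protein Kinase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the systematic analysis of covalent
    and allosteric protein kinase inhibitors from public bioactivity and
    structural data. Provides compound standardization (salt stripping,
    charge neutralization, stereochemistry removal, canonical SMILES),
    high-confidence activity curation and log-scale potency aggregation,
    electrophilic warhead detection by SMARTS substructure matching,
    analogue-series decomposition by the compound-core relationship
    method with covalent/non-covalent analogue-pair extraction, potency
    statistics (one-way ANOVA, Tukey-Kramer post hoc, paired t-tests),
    multi-kinase promiscuity profiling, and a triage protocol for X-ray
    structures of kinase-ligand complexes. A deterministic synthetic-data
    generator emulates multi-source activity tables and structure files
    so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
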