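Package: scaffquery
Title: Ligand-Based Drug Repurposing via Enriched Scaffold Substructure Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-testable pipeline for ligand-based in silico drug
    repurposing. Harvests target-to-ligand evidence from the payload formats of
    five public data services (Open Targets, UniProt, PDBe, RCSB PDB, ChEMBL,
    Guide-to-Pharmacology), standardizes compound structures (stereo removal,
    salt stripping, charge neutralization, element filtering, InChIKey
    identity), converts bioactivities to the negative-log (pX) scale and
    assigns binary activity labels, extracts Bemis-Murcko scaffolds, clusters
    them by maximum-common-substructure distance, emits one SMARTS structural
    query per scaffold cluster, and screens drug libraries by substructure to
    nominate repurposing candidates. Ships a synthetic-data generator that
    plants scaffold families with known ground truth so the whole pipeline can
    be exercised and validated without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
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
    tools,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
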