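Package: karyoshift
Title: Aneuploidy Pattern Analysis for Unstable Hybrid Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chromosome copy-number instability in yeast
    strain panels and interspecific hybrids. Infers per-chromosome population
    frequencies from windowed read-depth profiles against an expected
    per-haploid-copy coverage baseline, computes per-chromosome aneuploidy
    frequency statistics over strain x chromosome copy-number matrices and
    their correlation with chromosome size, evaluates chromosome-level
    enrichment of gene features (physical and genetic interactions, protein
    complex membership, stress up-regulation) against bootstrap null
    distributions of equally sized random gene sets, and builds a signed
    chromosome-pair epistasis matrix with a directed least-epistasis network.
    Includes seeded generators for every input type so the whole pipeline is
    testable on synthetic data with planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
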