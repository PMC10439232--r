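Package: plasmidforge
Title: In-Silico Modular Golden Gate Cloning and CRISPR Genome-Engineering Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic sequence-level simulation and planning of modular
    CRISPR/Cas9 cloning workflows in yeast: Type IIS (Golden Gate) digestion and
    one-pot assembly at three hierarchy levels, promoter and gene-disruption
    vector assembly with fluorescent dropout screening, homology-arm exchange
    between assembled and empty integration vectors, Cre-lox (lox66/lox71)
    selectable-marker excision, lambda-Red single-oligonucleotide recombineering
    for re-encoding guide RNAs on Cas9 helper plasmids, protospacer scanning and
    cut-site computation, homology-arm design and homologous-recombination
    integration into a genome, and normalization of promoter-strength
    fluorescence assays. Ships a seeded generator for a synthetic mini-toolkit
    (annotated GenBank plasmids and a toy multi-chromosome genome) so every
    operation is verifiable without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
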