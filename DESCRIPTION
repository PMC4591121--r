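Package: sigma54scan
Title: Genome-Wide Analysis of Sigma54 Binding Sites from ChIP-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping and characterizing binding sites of the
    bacterial alternative sigma factor sigma54 (RpoN) from ChIP-seq coverage
    tracks. Implements fold-above-threshold (FAT) peak calling, construction
    and scanning of a 17-column -24/-12 promoter position-specific scoring
    matrix, classification of sites as intergenic or intragenic in sense or
    antisense orientation with predicted transcription start sites and
    positional statistics, strand-resolved median RNA polymerase occupancy
    meta-profiles, and cross-species conservation scoring of binding sites
    with a consensus-position substitution-rate contrast. A synthetic-data
    module generates genomes with planted motifs, simulated ChIP coverage,
    and neutrally diverged ortholog genomes so the whole pipeline can be
    exercised end to end without external data. Ships a transcription of the
    135 published Escherichia coli sigma54 binding sites as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
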