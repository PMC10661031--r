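Package: moclosim
Title: Golden Gate Assembly Simulation and Design Automation for Modular Yeast Toolkits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico genetic-design-automation engine for hierarchical
    Golden Gate (MoClo-style) cloning in budding yeast. Simulates Type IIS
    restriction-ligation assembly under the modular yeast-toolkit (YTK-style)
    part grammar (Level-1
    transcriptional units, Level-2 multigene constructs of up to ten units,
    BbsI marker swapping), plans NotI-release gap-repair assemblies with
    junction-amplicon prediction, designs multiplexed gRNA-tRNA arrays,
    selects genomic integration loci from FASTA/GFF3 input, and ships a
    deterministic generator of a toy kit and toy genome so every workflow is
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
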