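Package: fusionscope
Title: Characterization of Fusion Transcripts from RNA-Seq Fusion Calls
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize chimeric (fusion) transcripts in plant
    transcriptomes starting from the breakpoint calls of read-level fusion
    detection tools. Classifies each fusion junction by chromosomal locality,
    coincidence with annotated exon boundaries, donor/acceptor splice-site
    dinucleotides (canonical GT-AG versus non-canonical), short homologous
    sequences (microhomology) flanking the breakpoints, and reading-frame
    preservation. Merges calls across tools and samples into unique fusions
    and parental gene pairs, filters long-read alignment evidence, computes
    parental-gene co-expression and fusion-present versus fusion-absent fold
    changes, performs 2^-ddCt relative quantification of qPCR data, builds
    presence/absence conservation matrices across genotypes with hierarchical
    clustering, and benchmarks fusion callers by sensitivity, precision and
    F-measure. A seeded synthetic-data generator plants fusions of known
    mechanism in a toy genome so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
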