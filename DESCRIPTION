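Package: plastomics
Title: Comparative Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of angiosperm plastomes: detection
    of the quadripartite structure (LSC/IRb/SSC/IRa) and inverted-repeat
    junction genes, microsatellite (SSR), dispersed and tandem repeat
    scanning, alignment-based SNV/InDel calling with per-region mutation
    rates, sliding-window nucleotide diversity with hotspot detection, a
    complete codon-usage-bias suite (RSCU, ENC, CAI, CBI, Fop, ENC-plot and
    PR2-plot coordinates, optimal-codon determination), and pairwise
    Nei-Gojobori Ka/Ks with functional-category comparisons. A synthetic
    plastome evolver generates annotated quadripartite genomes along a
    phylogeny with ground-truth event logs so every analysis is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
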