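Package: polyTE
Title: Population Genetics of Polymorphic Transposable Element Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide population-genetic analysis of human polymorphic
    transposable element (polyTE) presence/absence genotypes (Alu, L1, SVA).
    Reads mobile-element-insertion VCF genotypes and population panels; computes
    per-locus insertion allele frequencies, frequency spectra, continental
    sharing/exclusivity, the delta ancestry-informativeness statistic and
    Weir-Cockerham F_ST; builds allele-sharing distance matrices, classical MDS
    embeddings and neighbor-joining population trees with a hypothetical
    insertion-free ancestor; estimates supervised admixture fractions by
    maximum likelihood (EM over the ancestry simplex); and evaluates
    marker-subset ancestry prediction by cross-validation. A synthetic-data
    generator with full ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
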