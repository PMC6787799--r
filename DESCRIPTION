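Package: topobeta
Title: Topological Beta-Diversity and Matched Population Diversity of
    Symbiotic Gene Pools
Version: 0.1.0
Authors@R:
    person("Pool", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of matched population diversity between interacting
    symbiotic gene pools, such as a legume Nod-factor receptor gene pool and
    the rhizobial nodA gene pools sampled from nodules and soil. Provides
    pooled-amplicon nucleotide diversity (pi) with bootstrap and rarefaction,
    Spearman concordance of diversity rankings across host species,
    polymorphism-level selection statistics (pN, pS, pN/pS by Nei-Gojobori
    counting, and Tajima's D) with Welch contrasts, greedy identity OTU
    picking with neighbor-joining trees and biovar-clade filtering, and a
    topological beta-diversity statistic (Delta-G): a Procrustes-minimized
    L2 distance between Gaussian-mixture embeddings of frequency-weighted
    haplotype cluster sets, with bootstrap inference via one-sided
    Mann-Whitney tests and mutual k-nearest-neighbor tanglegrams. A
    synthetic-data generator produces plant/nodule/soil pool triplets with
    controlled diversity ranking, clade structure, codon-aware mutation and
    site-frequency-spectrum skew, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
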