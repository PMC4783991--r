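Package: allelescan
Title: Pseudogene Allele Scanning, Diversity and Phylogeny for a Myrosinase Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates splice-aware gene models on allele sets of a plant
    myrosinase locus, detects and types frame-shift insertions/deletions and
    splice-border mutations against a reference functional allele, calls each
    allele functional or disabled, computes partitioned population-diversity
    statistics (haplotype diversity, nucleotide diversity, Watterson's theta,
    SNP and indel densities), and builds Tamura-Nei distance / neighbor-joining
    phylogenies with a parsimony count of independent gene-disabling events.
    Includes a synthetic allele-population simulator with a planted-mutation
    truth ledger for end-to-end validation.
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
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
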