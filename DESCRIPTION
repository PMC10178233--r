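Package: its2gc
Title: Structure-Partitioned GC Evolution Analysis of ITS2 Allele Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying GC-content evolution of the ribosomal
    internal transcribed spacer 2 (ITS2) in the context of its conserved
    secondary structure. Reads aligned sequence-structure (Vienna triplet)
    allele sets, derives a consensus secondary structure and partitions
    alignment columns into paired and unpaired regions, computes GC content,
    GC homogeneity and the average number of pairwise nucleotide differences
    (K), fits nucleotide and 16-state base-pair (doublet) substitution
    models by maximum likelihood or MCMC with AICc model selection, and
    derives equilibrium GC content (GC*), base-pair formation rates into
    GC-type versus AU-type pairs, and mismatch-conversion bias, to test the
    GC-biased gene conversion (gBGC) hypothesis. Includes a synthetic
    ITS2-family generator with tunable homogenization and GC bias so the
    whole analysis runs on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
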