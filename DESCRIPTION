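Package: OGlycoAtlas
Title: Cross-Species Consolidation and Quantification of the Neuronal
    O-Glycoproteome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building an expanded map of mucin-type O-GalNAc
    glycosylation sites on neuronal proteins and for the downstream
    quantitative analyses that accompany such a map. Animal glycosites are
    projected onto human orthologs through global pairwise protein alignment
    and retained when they land on Ser/Thr/Tyr; human-native and
    animal-conserved sites are consolidated into a non-redundant
    human-coordinate site table with species and evidence provenance.
    Multi-batch TMT secretome experiments are normalized by sample-loading
    scaling and internal reference scaling (IRS) before differential
    secretion testing. Additional modules annotate glycosaminoglycan
    linkage-region (GAG stub) masses from elemental compositions, profile
    oligomer classes from mass-photometry landing events, summarize
    dense-core-granule morphometry, and normalize vesicular neurotransmitter
    uptake. Seeded synthetic-data generators emulate every input so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
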