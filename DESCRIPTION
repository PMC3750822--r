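Package: ampliTyper
Title: Replicate-Aware Genotyping of Multilocus Amplicon Sequencing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping highly duplicated loci (such as MHC class II
    exons) from dual-barcoded amplicon sequencing runs with two independent PCR
    replicates per individual. Implements a quality-filter cascade
    (length, barcode demultiplexing, IUPAC primer matching, Phred-quality and
    reading-frame checks), identical-read clustering with intra-amplicon
    artefact typology (PCR chimeras, 1-2 bp polymerase-error variants, more
    divergent artefacts), an iterative cross-replicate and cross-individual
    allele-calling workflow, maximum-likelihood estimation of per-allele
    relative amplification efficiencies under a multinomial read-count model,
    and the T1 family of minimum read-depth thresholds for reliable genotyping
    (exact inclusion-exclusion, multinomial simulation under unequal
    efficiencies, per-amplicon resampling, and minimum-efficiency grids).
    A read-level simulator with full truth tables emulates the error taxonomy
    of 454-style amplicon runs for validation and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
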