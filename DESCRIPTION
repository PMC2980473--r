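Package: transprot
Title: Trans-Organism Proteome Characterization Against Near-Neighbor Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how peptide and protein identifiability decays with
    16S rDNA evolutionary distance when tandem-MS spectra from one bacterium
    are searched against the genome of a sequenced near neighbor. Provides
    in-silico tryptic digestion and peptide-to-protein indices, E-value
    filtering of peptide-spectrum matches with the two-unique-peptide protein
    rule, pairwise 16S distances from global alignment, normalized
    observation ratios, one-phase exponential decay and four-parameter
    logistic fits with 95 percent prediction bands, genomic coverage-gap
    detection, and a clade simulator so the full pipeline can be exercised
    and validated without raw mass-spectrometry data. Supports
    characterization of unsequenced isolates against a panel of sequenced
    neighbors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
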