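Package: apobecsig
Title: APOBEC3 Mutational Signature Analysis on Synthetic Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of APOBEC3B-driven somatic mutagenesis in
    tumor whole genomes. Provides a truth-annotated synthetic tumor-genome
    generator (planted SBS-96 signature mixtures, indels, structural variants,
    replication-timing bias, read-support metadata), Mutect2-style quality
    filtering, pyrimidine-normalized SBS-96 and indel/SV spectra, the TCW
    APOBEC enrichment score with one-sided exact-test significance and
    Benjamini-Hochberg stratification, signature refitting and de novo
    non-negative matrix factorization extraction, replication-timing and
    mutation-clustering topography, and cohort-level statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
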