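Package: paness
Title: Screen Variants for Novel Essential Splice-Site Creation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens single-nucleotide variants in VCF data for low-frequency
    alleles that create novel essential splice-site dinucleotides (GT donor or
    AG acceptor) on the transcribed strand of overlapping transcripts. Each
    candidate is reported with its sequence context, a weighted similarity
    score against the classical mammalian splice-site consensus, and the
    distance to the nearest canonical site of the same type. Companion tools
    predict the protein consequence of skipping a single exon (reading-frame
    arithmetic, premature-stop localisation, HGVS p. notation, a
    nonsense-mediated-decay flag), filter trios for Mendelian inheritance
    patterns, and generate fully synthetic genomes, gene models and planted
    variant sets with ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    tibble,
    methods,
    stats,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
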