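Package: top1tam
Title: Analysis of Topoisomerase 1 Transcription-Associated Indel Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for attributing short-deletion mutational signatures to
    topoisomerase 1 (TOP1) activity at genome-embedded ribonucleotides.
    Classifies deletions by short-tandem-repeat and microhomology context,
    scores the TNT sequence motif against genomic and matched-repeat null
    models, compares indel spectra (cosine similarity with a
    Dirichlet-multinomial null and bootstrap-supported clustering), estimates
    mutation rates from fluctuation assays by the Lea-Coulson method of the
    median, stratifies deletion burden by gene expression and TOP1 activity,
    and redesigns reporter coding sequences to maximize dinucleotide repeat
    content. A synthetic-data module generates genomes, deletion sets,
    colony-count distributions, expression tables and binned activity tracks
    with truth labels so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    Biostrings,
    readr,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
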