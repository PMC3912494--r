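Package: imprintscan
Title: Ab Initio Imprinted-Gene Discovery from Histone-Mark Co-Occurrence and Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens gene promoters for the chromatin signature of genomic
    imprinting: concurrent, transcriptionally opposing histone modifications
    (H3K4me3 and H3K9Ac marks of activation together with the H3K9me3 mark of
    repression) plus an annotated CpG island, arising because chromatin
    immunoprecipitation pools the active and silenced parental alleles.
    Provides a Poisson local-background peak caller for treatment-versus-input
    ChIP coverage, interval overlap and Venn machinery with a strict
    full-overlap refinement tier, classification of candidate genes as
    imprinted, allele-biased, biallelic, or undetermined from allele-specific
    expression in reciprocal crosses, bisulfite clone methylation
    summarization with allele-partitioned differential-methylation testing,
    and a seed-reproducible synthetic-data generator with planted truth so
    the whole pipeline can be exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
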