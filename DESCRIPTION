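Package: cistromeCT
Title: Integrative Statistics Linking Transcription-Factor Cistromes to
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Connects differential transcription-factor binding (cistromes)
    to differential gene expression (transcriptomes). Implements the
    weighted cistrome-transcriptome (wt-C-T) score, a distance-decayed sum
    of peak significance around each gene's transcription start site
    multiplied by the gene's absolute fold change, with Wilcoxon rank-sum
    comparison of score distributions between cell backgrounds; minimum
    1-bp interval overlap statistics with a binned chi-squared test;
    cooperative/antagonistic gene-concordance classification between paired
    differential-expression contrasts; hypergeometric enrichment of
    annotated classes in protein-complex membership lists; delta-NES
    tables; delta partial-correlation analysis of coregulator influence;
    and bootstrap Jaccard similarity of ranked gene lists. A seeded
    synthetic-data generator plants known effects (peak-to-gene coupling,
    antagonism fractions, latent confounders, top-k rank overlap) so every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
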