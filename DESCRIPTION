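Package: ighvpop
Title: Germline and Expressed-Repertoire Analysis of IGHV Allelic and
    Copy-Number Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising immunoglobulin heavy-chain variable
    (IGHV) gene diversity from full-length germline amplicon sequencing and
    bulk IgM repertoire sequencing. Implements primer trimming, quality and
    abundance filtering, dereplication, closest-match allele assignment with
    novel-allele naming, regulatory-region (leader, intron, recombination
    signal sequence) variant calling, leader-sequence classification
    (reference / SNV / mismatch), allele-count copy-number genotyping,
    IGHJ-anchored haplotype reconstruction with a binomial Bayes-factor
    confidence, chromosome-resolved duplication calling, duplication-linked
    expression fold change, and germline-versus-transcriptome concordance
    reporting. A seeded synthetic-data generator emits ground-truth diploid
    genotypes, germline amplicon reads, and anchored VDJ repertoires so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
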