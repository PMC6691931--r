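Package: chic2drug
Title: Drug Repositioning from Promoter Capture Hi-C Chromatin Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links genome-wide association study (GWAS) risk loci to candidate
    causal genes using Capture Hi-C chromatin interactions filtered by
    ChromHMM chromatin states, then maps those genes to existing drug targets
    to nominate repositioning opportunities for autoimmune rheumatic diseases.
    Interactions are retained when the SNP-side restriction fragment carries an
    enhancer state and the partner fragment carries a promoter state in the
    same cell type; genes whose transcription start site lies in the promoter
    fragment and which are expressed in a relevant cell type become candidates.
    Candidates are compared with the gene reported by the source GWAS, joined
    to a DrugBank-style drug-target table with indication-text matching, and
    refined by one-sided Fisher's exact pathway enrichment with
    Benjamini-Hochberg false discovery rate control. A deterministic
    synthetic-data generator plants ground-truth loci, drugs and enriched
    pathways so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stringr,
    withr,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
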