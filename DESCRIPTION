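Package: cgiplast
Title: Pan-Cancer Classification of CpG-Island Promoter Regulation and
    Polycomb Target Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates CpG-island (CGI) promoters from TSS, methylation-probe
    and CGI annotation, annotates Polycomb (PRC2) occupancy from chromatin
    states and EZH2/SUZ12 binding, and calls per-cancer-type gene classes
    (hypermethylated PRC2+, upregulated PRC2+, upregulated PRC2-) from
    tumor/normal expression counts and methylation beta values. Downstream
    statistics cover regulatory plasticity, cancer-type-restricted genes,
    PCA distance ratios, reciprocal gene-set and motif enrichment,
    enhancer-to-gene link summaries and TSS-centered chromatin profiles.
    Ships a synthetic multi-cancer cohort generator with planted ground
    truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
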