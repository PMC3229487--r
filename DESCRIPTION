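Package: ssrpop
Title: Population Structure, Diversity and Linkage Disequilibrium for SSR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiallelic simple sequence repeat (SSR) genotype
    panels from inbred plant germplasm collections. Reads and validates
    genotype tables, genetic maps and morphological trait tables; classifies
    rice varieties into indica/japonica categories by Cheng's index; computes
    allele frequencies, gene diversity, polymorphism information content,
    modified Rogers distance and Gst with per-locus genome scans and bootstrap
    standard errors; infers population structure by PCA, principal coordinate
    analysis, Laplacian embedding and Gaussian-mixture clustering with BIC
    model selection and the Evanno delta-K statistic; measures marker-number
    sufficiency by random and stratified marker resampling; and quantifies
    multiallelic linkage disequilibrium (weighted D', r-squared, permutation
    significance), LD decay against the unlinked-pair quantile, and LD blocks
    on the genetic map. A seeded synthetic-panel generator emulating a
    two-subpopulation selfing panel makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
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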