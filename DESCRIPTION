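Package: poolscan
Title: Comparative Pool-Seq Genome Scans for Local Adaptation and Convergent Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genome scans from pooled whole-genome
    sequencing (Pool-seq). Reads pooled variant calls (VCF with per-pool
    read depths), gene annotations (GFF3) and ortholog tables; applies
    standard post-calling SNP filters; computes per-SNP pool-corrected
    FST and 50-kb windowed expected heterozygosity; aggregates statistics
    to genes across ortholog maps; identifies top-candidate genes for
    local adaptation with a binomial outlier test; and tests for
    convergent evolution between species pairs with the Null-W
    rank-based test. Includes a synthetic Pool-seq data generator
    (Balding-Nichols differentiation with planted selection) so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    ape,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
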