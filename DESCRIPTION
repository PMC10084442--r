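Package: clonering
Title: Clonal and Spatial Population Genetics of Truffle Fairy Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clonal population genetics of heterothallic
    ascomycetes genotyped at haploid microsatellite (SSR) panels plus the
    mating-type locus. Assigns multilocus genotypes (MLGs) and tests their
    clonality with Monte-Carlo Psex significance, clone-corrects datasets,
    and computes genotypic richness, Simpson diversity and evenness, and
    unbiased gene diversity. Infers paternal genotypes from pooled
    ascospore extracts, reconstructs zygotes and their inbreeding
    coefficient, and detects hermaphroditic genets. Spatial statistics
    include the nearest-neighbour aggregation index with permutation
    tests, clonal subrange, Mantel isolation-by-distance, Loiselle kinship
    autocorrelation by distance class and the Sp statistic, and
    AMOVA-based PhiPT differentiation for haploid data. A qPCR module
    fits ITS standard curves, converts copy numbers to soil mycelium
    mass, and estimates fairy-ring growth rates and ages. A synthetic-data
    module simulates fairy-ring and multi-genet populations with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
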