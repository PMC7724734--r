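Package: symbiophy
Title: Host-Endosymbiont Phylogenetics, Strain Typing and Cophylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for endosymbiont screening surveys: Kimura
    two-parameter distances with explicit gap handling, neighbour-joining
    trees with bootstrap support, endosymbiont strain delimitation from
    clade support with supergroup assignment, standardized phylogenetic
    host-specificity scores with permutation nulls, ParaFit tests of
    host/symbiont phylogenetic congruence with Cailliez-corrected
    principal coordinates, event-based cophylogeny reconciliation
    (cospeciation, duplication, host shift, loss, failure to diverge)
    with exact and population-based search plus random tip-mapping
    significance, and prevalence / tissue-tropism / sex-effect
    statistics. Includes generators for joint host-symbiont histories,
    sequence evolution along trees, and specimen screening tables so
    every stage can be exercised on data with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    jsonlite
Config/testthat/edition: 3
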