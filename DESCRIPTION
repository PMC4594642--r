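Package: karyorate
Title: Rates of Karyotype Evolution and Long-Term Effective Population Size
    from Chromosome-Painting Homology Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying karyotype evolution from cross-species
    chromosome-painting (zoo-FISH) homology maps. Parses syntenic-block
    homology tables and dated phylogenies, reconstructs ancestral syntenic
    associations by Fitch parsimony, counts fusion and fission events
    between ancestral and derived karyotypes, computes per-branch fixation
    rates with divergence-time error bounds, and estimates long-term
    effective population size by inverting the diffusion rate equation for
    underdominant chromosomal rearrangements. Includes a forward
    Wright-Fisher simulator used as a stochastic cross-check of the
    diffusion formula and a synthetic karyotype-evolution generator with
    ground-truth event logs for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
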