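Package: reefdd
Title: Morpho-Functional Diversity Dependence in Fossil Reef Corals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing diversity dependence among morpho-functional
    groups of fossil reef corals. Curates Paleobiology-Database-style
    occurrence tables, builds morpho-functional groups from binary growth-form
    scores, computes functional redundancy and over-redundancy indices with
    permutation null models, estimates origination and extinction times and
    rates from fossil occurrence series with a reversible-jump MCMC under
    Poisson preservation models, and fits trait-dependent extinction (MTE)
    and multivariate covariate-dependent birth-death (MBD) models with
    horseshoe shrinkage. A forward birth-death simulator with known truth
    supports end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
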