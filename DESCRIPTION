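Package: kinshare
Title: Kin-Directed Food Transfers in Subsistence Societies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dyadic analysis of intergenerational food
    transfers in small-scale subsistence societies. Generates synthetic
    communities (multi-generation pedigrees, age- and sex-specific caloric
    production and consumption schedules, and transfer allocation driven by
    Hamilton's rule, b*r > c, with diminishing returns to consumption);
    computes pedigree relatedness with a gene-dropping validation oracle;
    reduces production-and-sharing interview ledgers to antisymmetric dyadic
    net-transfer matrices at the individual and nuclear-family level; builds
    measured and instrumental (composition-based) net-need indices; and fits
    mixed-effect models of net transfers on relatedness, need, and their
    interaction, plus age-sex transfer profiles by relationship category.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    yaml,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
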