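Package: nutriflows
Title: Nutrient Flow Accounting and Vulnerability Analysis for Marine Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts marine fisheries catch and trade records into nutrient
    masses and recommended-nutrient-intake (RNI) equivalents, computes
    foreign-fishing and trade balances with flag-of-convenience adjustment,
    aggregates nutrient flows across categories of inadequate micronutrient
    intake, and scores national vulnerability of fishery-derived nutrient
    supply with a composite exposure/sensitivity/adaptive-capacity index,
    with and without climate exposure. Ships a seeded synthetic-world
    generator emulating the schemas and closure properties of global catch
    and trade reconstructions so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
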