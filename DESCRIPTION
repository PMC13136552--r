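Package: branchcarbon
Title: Branch-Level Carbon Balance of Sun and Shade Branches in Tree Crowns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the carbon balance of individual tree
    branches along the vertical canopy light gradient. Fits exponential
    photosynthetic light-response curves to gas-exchange observations,
    builds temperature-corrected sub-daily gross photosynthesis and dark
    respiration series from continuous irradiance logger records,
    integrates them to daily net carbon assimilation, and relates branch
    construction costs (carbon in current-year foliage and twigs) to
    cumulative assimilation via amortisation times and relative carbon
    costs (RCC). Includes a one-at-a-time sensitivity analysis that swaps
    shade-branch inputs for sun-crown values, a module for the relative
    cost of seasonal starch build-up with geometric branch-biomass
    upscaling, a synthetic scenario generator with known ground truth for
    validation, and delimited-table readers/writers plus an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
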