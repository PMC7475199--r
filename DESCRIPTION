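Package: ffvpsim
Title: Agent-Based Simulation of Healthy-Food Preference Learning Under a
    School Fruit and Vegetable Program
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An agent-based model of how elementary-school children form
    preferences for healthy food under the USDA Fresh Fruit and Vegetable
    Program (FFVP). Agents update a perceived valuation of healthy food by
    temporal-difference learning, face daily food situations whose mix is
    governed by food-desert status and FFVP receipt, choose by the Luce rule,
    and map learned preference to daily servings through the Poisson quantile
    function. The package provides a synthetic cohort generator emulating the
    FFVP-by-food-desert structure of an administrative school cohort, a fast
    daily-step simulator over kindergarten through grade 6, calibration of the
    environment parameters to an empirical one-year program effect, and
    reporting of group contrasts (Welch t tests), exposure-pattern summaries,
    and preference-trajectory panels.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
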