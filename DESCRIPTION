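Package: fortiscan
Title: Identify Fortified Foods in Branded-Food Label Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based identification of micronutrient-fortified foods in
    branded-food databases from label data alone. Implements a seven-step
    decision tree grounded in EU food-labeling legislation (EU 1169/2011)
    that classifies every food as fortified, non-fortified, or ineligible
    per nutrient from its Dutch ingredient list, declared nutrient values,
    legal name, and mandatory particulars, keeping a replayable step trace.
    Ships the nutrient significance thresholds, a Dutch fortificant and
    food-additive lexicon, validation statistics (contingency tables,
    sensitivity and specificity, Sison-Glaz simultaneous multinomial
    confidence intervals), and a seeded synthetic label-data generator with
    per-record ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
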