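Package: randflora
Title: Birth-Death Diversification Rates and Timing of Rand Flora
    Disjunctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Meta-analysis toolkit for dated continental disjunctions in the
    African Rand Flora. Implements method-of-moments net diversification
    estimators from clade size and crown or stem age under fixed extinction
    fractions, clade-size tail probabilities and expected-diversity confidence
    envelopes under the constant-rate birth-death process, an event-driven
    birth-death simulator (with episodic extinction pulses) serving as Monte
    Carlo oracle and synthetic-data generator, chronogram age extraction
    (crown, stem and disjunction ages from ultrametric trees), and geological
    stage binning of disjunction ages. Ships a packaged lineage/disjunction
    table encoding 21 dated Rand Flora splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
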