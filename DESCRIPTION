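Package: beeshare
Title: Attraction-Choice Models of Pollinator Sharing Between Co-Flowering Plants
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic consumer-resource models of pollination
    facilitation and competition between two co-flowering plant species
    (a focal crop and a wildflower "competitor"). Pollinators are drawn
    to a patch by a joint attraction function N(c, w) and divide among
    the species by input matching (ideal free distribution), giving
    visit rates F = N * D. The package evaluates F under a menu of
    attraction functions (linear, local-pool, weighted, decelerating,
    saturating, sigmoid Holling type III, and a two-species saturating
    form), computes the closed-form optimal competitor amount w* and
    the facilitation threshold c0 for the saturating model, optimizes
    the fixed-area trade-off (Model B) for the crop-yield optimum p*,
    classifies parameter combinations into facilitation, neutrality or
    competition, detects interspecifically precipitated Allee effects,
    and reproduces the figure data tables via a sweep runner and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
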