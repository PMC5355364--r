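Package: exomatch
Title: Exome-Matched Dietary Amino Acid Design and Limiting-Nutrient Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives an organism's dietary amino-acid requirement ratio by
    summarising the amino-acid usage of its in silico-translated
    protein-coding exome, scores any diet for its limiting essential amino
    acid under a Liebig-style minimum rule with conditional amino-acid
    substitution, predicts relative reproductive or growth output between
    diets together with single amino-acid supplementation breakpoints and
    piecewise response curves, designs maximally mismatched control ratios
    by constrained optimisation on the probability simplex, and tests
    whether a gene set's amino-acid usage is unusually close to the exome
    average with a rank-based null. Includes a deterministic synthetic
    proteome generator and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
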