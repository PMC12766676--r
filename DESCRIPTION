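Package: sunburstmeta
Title: Meta-Analysis of Sunburst-Maze Path-Choice Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing single-trial path-choice data from
    Sunburst-maze shortcutting experiments. Provides a resampling-based
    chance model for per-path choice percentages with derived significance
    thresholds, chance normalization (z) for cross-experiment comparison,
    experiment categorization by preferred path role with a
    shortcut-first priority rule, paired cross-experiment contrasts with
    sign-flip permutation tests, chi-square tests of expected proportions
    with Benjamini-Hochberg correction, and a synthetic-experiment
    generator that simulates navigation strategy mixtures (shortcutting,
    adjacency, beaconing, thigmotaxis, uniform exploration) so that every
    pipeline stage can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    readr,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
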