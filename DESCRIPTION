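Package: seedcoex
Title: Seed-Gene Spatial and Differential Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rank-based co-expression analysis centred on a single seed gene.
    Computes spatial co-expression between a seed gene and a gene set across
    brain regions within donors, tracks the seed-to-set correlation over donor
    age with random-gene-set and seed-replacement specificity nulls, and tests
    rewiring of the seed-to-set correlation between case and control cohorts
    (paired Wilcoxon, label-permutation and inversion-proportion statistics),
    with Fisher and direction-aware Fisher combination of per-study p-values.
    Includes a latent-factor simulator that generates multi-donor spatial and
    case/control cohort data with known ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
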