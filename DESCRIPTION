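Package: suturekit
Title: Cranial Suture Fusion Analysis Across Mammalian Ontogeny
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the degree, timing, and pattern of
    cranial suture fusion from ordinal fusion-score matrices collected
    over ontogenetic series. Computes weighted closure percentages per
    suture, specimen, species-stage, and Krogman region; builds fusion
    sequences and tests their concordance with the classical Krogman
    order and between species via Kendall tau-b with Bonferroni
    correction; estimates ancestral closure states under Brownian
    motion and fits phylogenetic generalized least squares regressions
    of fusion on skull size; derives continuous and discrete
    developmental-age proxies from centroid size; and generates fully
    synthetic ontogenetic datasets with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
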