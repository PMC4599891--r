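Package: poolscreen
Title: Deconvolution and Downstream Analysis of Pooled shRNA Fitness Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-color microarray deconvolution of pooled shRNA
    fitness screens and their downstream analyses. Implements background
    filtering and log2 R/G ratio computation, pool-wise quantile
    normalization with replicate QC, multiple-hairpin hit calling
    (enriched/protective vs depleted/lethal genes), RIGER-style second-best
    hairpin gene ranking with a permutation normalized enrichment score,
    zero-transformation and occurrence/fold filtering of expression
    matrices, two-class expression signature creation and projection with
    cross-signature regression, and protein-normalized metabolite fold
    change and substrate/product ratio statistics. Ships a synthetic-data
    generator with known ground truth (library structure, planted fitness
    effects, knockdown expression programs, metabolite panels) for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
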