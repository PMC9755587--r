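Package: exprofiler
Title: Expression-Profile Co-Expression Ranking and qPCR Relative Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking genes by similarity of their tissue expression
    profiles and for relative quantification of qPCR experiments. Expression
    profiles are mean-normalized per gene across a panel of tissue or stage
    samples (TPM in, dimensionless profiles out) and compared with an L1
    statistic (the sum over samples of absolute profile differences, "delta
    sum"), so that a query gene ranks first with distance zero and co-expressed
    genes follow with the smallest distances. The qPCR side covers standard-curve
    amplification-efficiency QC (slope, R-squared, efficiency bounds),
    multi-reference 2^-ddCt fold changes with technical/biological replicate
    structure, and control-versus-treatment testing by one-way ANOVA with
    Dunnett's multiple-comparison adjustment. Seeded generators for TPM matrices
    with planted co-expression modules and for Cq plates with known fold changes
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
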