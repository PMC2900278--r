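Package: smartpool
Title: Smart Pooling Designs and Sparse Decoding for Pooled Expression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Construct and certify expander-graph pooling designs for
    multiplexed gene-expression experiments, compute pooled (multiplex)
    measurements from per-sample profiles, and decode each gene's
    expression in every sample from fewer pooled measurements than
    samples via l1-minimization (basis pursuit) solved as a linear
    program. Includes a synthetic-data generator for sparse spike
    profiles with multiplicative measurement noise, Monte-Carlo recovery
    experiments, error metrics with sparsity-tail bound checking, and
    tab-delimited matrix readers/writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
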