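Package: mtmspike
Title: Multi-Task Masked Modeling of Multi-Region Neural Spiking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised modeling of trial-aligned, multi-region neural
    spiking data by multi-task masking (MtM). A temporal-token transformer with
    per-session stitching alternates between causal, neuron, intra-region and
    inter-region masking objectives under a Poisson emission model, with a
    learnable prompt token that identifies the active masking scheme and can be
    reused at test time to adapt the model to a downstream task. Includes a
    seeded multi-session spike-train simulator with region-coupled latent
    dynamics and behavior covariates, and a test-time-masking evaluation
    benchmark: co-smoothing, forward-prediction, intra- and inter-region
    bits-per-spike, plus choice and motion-energy decoding from inferred rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    glmnet,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
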