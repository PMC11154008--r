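Package: repurposeR
Title: Transcriptomic and Network-Based Drug Repositioning for ADPKD-Style Indications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable drug-repositioning toolkit combining four
    computational stages: disease gene expression matching (DGEM), a
    Kolmogorov-Smirnov connectivity-score variant of connectivity mapping
    with data-driven selection of the disease-signature configuration;
    consensus pathway enrichment over the leading-edge genes that drive
    drug-disease connectivity scores; treatment-link prediction on typed
    heterogeneous knowledge graphs via degree-weighted path counts and a
    small neural classifier; and mechanism explanation on a multiscale
    interactome via node-type-biased random walks with restart. A synthetic
    data module generates every input with planted ground truth so the full
    pipeline is quantitatively benchmarked without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    nnet,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
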