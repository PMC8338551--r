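Package: mobcea
Title: Decision-Tree Cost-Effectiveness Analysis of Stem-Cell Mobilization Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness model comparing chemotherapy-free
    (G-CSF with on-demand plerixafor) and chemotherapy-based (cyclophosphamide
    plus G-CSF with on-demand plerixafor) peripheral stem-cell mobilization in
    multiple myeloma from the societal perspective. Provides a declarative
    model-configuration format with payer-partitioned cost items, gamma/beta
    parameter distributions fitted from means and 95% confidence intervals,
    incremental cost-effectiveness ratios with dominance classification, net
    monetary benefit, and one-way (tornado), scenario and probabilistic
    (Monte Carlo, CEAC/CEAF) sensitivity analyses, together with a synthetic
    configuration generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
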