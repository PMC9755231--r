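Package: tplext
Title: Taylor's Power Law Extensions for Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-variance scaling analysis of host-associated microbial
    communities via Taylor's power law and its community-level (Type-I) and
    mixed-species (Type-III) extensions. Builds per-sample and per-OTU
    mean-variance point sets from OTU count tables, fits the power law
    V = a*M^b on the log-log scale with confidence intervals, classifies
    spatial heterogeneity (uniform, random, aggregated), relates the fitted
    heterogeneity exponent to geometric host skin-area models, and provides
    supporting diversity statistics (Shannon index, Kruskal-Wallis,
    Bray-Curtis, ANOSIM). Includes a synthetic community generator with
    controllable mean-variance exponents for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
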