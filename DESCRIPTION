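Package: spectmap
Title: Slow Collective Variables by Spectral-Gap Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns a few slow collective variables (CVs) from
    high-dimensional molecular configuration descriptors by training a
    feed-forward mapping to maximize the spectral gap of a Markov
    transition matrix estimated with an anisotropic diffusion kernel.
    Includes free-energy landscape estimation in the learned CV space,
    overdamped Langevin generators of metastable benchmark data with a
    known slow coordinate, pairwise-distance featurization, and a small
    command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
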