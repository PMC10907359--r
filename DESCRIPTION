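Package: opinionflow
Title: Social-Media Opinion Mining and Opinion-Policy Consensus Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how public opinion expressed in short
    social-media posts feeds back into emergency-policy adjustment. The
    package generates synthetic labelled microblog corpora, extracts
    keywords by TF-IDF, clusters keyword vectors into a four-dimension
    indicator system with K-means, summarises dimension-level public
    concern and a satisfaction statistic per event checkpoint, and couples
    the resulting discrete opinion states (support/neutral/oppose) to a
    two-state policy-intent hidden Markov model with trajectory sampling,
    ensemble averaging, forward filtering and Baum-Welch estimation. An
    end-to-end pipeline runner makes the whole analysis reproducible from
    a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
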