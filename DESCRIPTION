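Package: corvidcache
Title: Virtual-Bird Simulations of Corvid Caching and Re-Caching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulations of food caching, cache recovery and
    re-caching in corvids (western scrub-jays), driven by a declarative
    memory system with base-level activation and decay, inhibition of
    return, and logistic transient noise, plus stress-driven re-caching
    rules. Includes a ground-truth world model and session engines (an R
    reference engine and a fast C++ engine), replication harnesses for two
    classic onlooker experiments, matched-pairs Wilcoxon and Friedman rank
    tests, representative-run selection, and a (decay, noise,
    stress-threshold) robustness sweep.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
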