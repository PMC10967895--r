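Package: protargetmr
Title: Proteome-Wide Mendelian Randomization for Drug-Target Discovery
Version: 0.1.0
Authors@R:
    person("OA", "Targets Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate drug targets from
    molecular quantitative-trait-locus (pQTL/eQTL) and disease GWAS summary
    statistics. Implements cis-instrument selection (genome-wide significance,
    MHC exclusion, LD clumping, cis-window, F-statistic and palindrome
    filters), two-sample Mendelian randomization (Wald ratio and
    inverse-variance-weighted estimators with Cochran's Q, MR-Egger intercept
    and Steiger directionality diagnostics, Benjamini-Hochberg FDR),
    approximate-Bayes-factor colocalization with the five-hypothesis
    posterior, summary-data-based MR with the HEIDI linkage test, a four-tier
    target classification, and a phenome-wide MR side-effect screen. Ships a
    seeded generator of LD-structured regional summary statistics with known
    causal architecture so the whole pipeline can be exercised end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
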