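Package: fbagames
Title: Evolutionary Game Theory on Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes microbial fitness payoffs from stoichiometric
    metabolic models by flux balance analysis under gene-deletion,
    metabolite-leakage and cross-feeding constraints; enumerates all
    pure-strategy Nash equilibria of the resulting n-player games via an
    indicator integer linear program with an independent brute-force
    oracle; simulates replicator dynamics and in silico invasion
    experiments; and classifies the ecological games that emerge across
    leakiness and cost landscapes. Includes small synthetic fixture
    networks (public-good hydrolysis, two-amino-acid cross-feeding with
    pleiotropic or epistatic pathway coupling) so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
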