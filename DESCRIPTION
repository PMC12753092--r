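Package: ksdate
Title: Coalescent-Corrected Species Divergence Dating from Ks Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ancestral effective population size (Ne) from the
    variance of a Ks (synonymous-divergence) distribution and uses it to
    correct Ks-based species divergence times for the 2Ne coalescent bias.
    Includes a native two-species coalescent simulator for ortholog pairs
    (fast Ks path and explicit aligned sequence pairs), Jukes-Cantor
    multiple-hit correction, a simulation-trained variance-to-Ne model per
    substitution-rate category with an analytic large-Ne regime, divergence
    dating in generations and years, and runners for robustness experiments
    (sequence-length and post-divergence bottleneck sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    Biostrings,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
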