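Package: pirank
Title: Phylogenetic Informativeness Profiling and Marker Ranking
Version: 0.1.0
Authors@R:
    person("pirank", "developers", email = "pirank@example.org",
           role = c("aut", "cre"))
Description: Profiles the phylogenetic informativeness (PI) of molecular
    markers from per-site substitution rates estimated on a fixed
    chronogram, integrates the profiles into differential phylogenetic
    informativeness (DPI) over an epoch of interest, and evaluates how
    well DPI rankings predict topological accuracy and branch support.
    Includes a rate-heterogeneous sequence simulator (JTT amino acid and
    K2P nucleotide models on ultrametric trees), maximum-likelihood
    per-site rate estimation via Felsenstein pruning, gene-tree inference
    with bootstrap, aLRT and decay-index supports, Robinson-Foulds
    evaluation against a reference topology, and the paired
    predicted-versus-empirical performance statistics (PPP/EPP) and
    cumulative support-path analyses used to validate marker ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
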