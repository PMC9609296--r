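Package: swimpars
Title: Total-Evidence Parsimony Tools for Swimming-Crab Morphotype Evolution
Version: 0.1.0
Authors@R: person("swimpars", "maintainers", email = "swimpars@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for total-evidence maximum-parsimony analysis
    of portunoid crabs and the P5-swimming-crab morphotype: a dependency-aware
    morphological character catalog with inapplicability logic, supermatrix
    assembly from aligned gene partitions and chimeric operational taxonomic
    units, equal-weights Fitch parsimony with heuristic tree search, strict
    consensus and nonparametric bootstrap, unordered-parsimony ancestral state
    reconstruction, a rule-based morphotype classifier, and simulators for
    trees, hierarchically coded morphological characters and GTR+G+I
    nucleotide partitions so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
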