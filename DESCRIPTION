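Package: plexanneal
Title: Multiplex PCR Primer Set Design by Simulated Annealing on a
    Primer-Dimer Likelihood Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs highly multiplexed PCR primer sets that minimize
    predicted primer-dimer formation. Primer candidates are generated per
    target by trimming proto-primers to a nearest-neighbor free-energy
    window, admissible forward/reverse pairs are enumerated under amplicon
    length and pivot-containment constraints, and one pair per target is
    selected by simulated annealing on a rapidly computable dimer-likelihood
    loss. The pairwise score sums 2^len * 2^numGC / ((d1+1)(d2+1)) over all
    reverse-complementary subsequences of length 4-8 between two primers,
    and the set-level loss is evaluated in O(N*P) time through a subsequence
    hash table with incremental updates under single-pair swaps. Companion
    tools classify amplicon sequencing reads as on-target, dimer or
    non-specific, tabulate per-primer-pair dimer read counts, and quantify
    prediction accuracy against observed dimers via sensitivity,
    specificity and ROC analysis. A seeded synthetic-data generator
    produces target fixtures and simulated read libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
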