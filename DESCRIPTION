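Package: tcrconv
Title: TCR Beta Repertoire Convergence, Clonality, and Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing T cell receptor beta (TCRB) clonotype
    tables: reading and writing AIRR-flavored and ImmunoSeq-flavored
    tab-separated clonotype files; repertoire statistics including Shannon
    diversity, evenness, clonality, convergent-recombination frequency and
    Jaccard clonal overlap; a substitution sequencing-error artifact model
    that predicts spurious convergence from per-clone read depth, CDR3
    length, and a per-base error rate, with grid-based error-rate fitting
    by Spearman correlation; a two-feature (convergence, clonality)
    logistic-regression response classifier with repeated leave-group-out
    cross-validation, pooled ROC/AUC, and Youden-optimal operating point;
    and a synthetic V(D)J repertoire simulator with planted convergent
    groups, multinomial read sampling, and read-level substitution-error
    injection carrying full ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
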