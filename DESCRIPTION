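Package: sefreq
Title: Multiview Neighborhood-Regularized Matrix Factorization for Drug
    Side-Effect Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the frequency class (very rare to very frequent) of
    drug-side-effect pairs by class-weighted non-negative matrix
    factorization with a Gaussian prior on unknown pairs, regularized by
    k-nearest-neighbour graph Laplacians built from several similarity
    views of drugs (side-effect frequency profiles, chemical fingerprints,
    GO annotations of targets) and of side effects (frequency profiles,
    MedDRA terms), with adaptively learned view weights.  Includes
    cold-start embedding refinement for drugs or side effects without any
    known frequencies, warm- and cold-start cross-validation protocols
    with per-drug ranking metrics, a synthetic-data generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    ChemmineR,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
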