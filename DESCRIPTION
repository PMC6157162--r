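Package: mircascade
Title: Cascade Dirichlet-Process Mixture Modelling for microRNA Target
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric Bayesian clustering of microRNA-mRNA binding
    sites for target prediction.  Interactions are described by sequence,
    pairing, accessibility and positional features, clustered with a
    Dirichlet-process Gaussian mixture model (Chinese-restaurant-process
    prior, fixed component variance, conjugate standard-normal prior on
    component means, BIC-driven parameter selection), and refined into a
    cascade (divisive) cluster tree whose leaves are homogeneous in the
    participating miRNA or transcript.  Includes tiered negative-set
    synthesis from sliding transcript windows, t-test / AUC / recursive
    feature elimination, transcriptome screening by iterated local
    complementarity alignment, and a probabilistic interaction-confidence
    score for ranking predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
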