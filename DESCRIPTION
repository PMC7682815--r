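Package: ncrnafam
Title: Short Non-Coding RNA Family Classification from Raw Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the functional family of short (<= 200 nt) non-coding RNA
    sequences from raw sequence alone, without secondary-structure features.
    Provides lightweight sequence encodings (non-overlapping k-mer one-hot
    vectors and Hilbert, Morton and Snake space-filling-curve grids under
    random, constant or new-symbol padding), convolutional and bidirectional
    LSTM classifiers trained with categorical cross-entropy, homology-aware
    train/validation/test splitting by normalized Hamming similarity,
    boundary-noise injection and dinucleotide-preserving shuffling for
    robustness and rejection experiments, Monte Carlo Dropout uncertainty
    estimation with Information Entropy and Top Difference rejection rules,
    and multi-class evaluation metrics (accuracy, Cohen's kappa, Matthews
    correlation, per-class F1, ROC-AUC). A synthetic multi-family sequence
    generator with planted motifs supports fully offline testing.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
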