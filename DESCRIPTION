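Package: imspeech
Title: Multi-Condition EEG Decoding of Imagined Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether EEG recorded during overt (pronounced)
    speech can improve the decoding of imagined speech. Provides a synthetic
    generator of epoch-structured multi-channel EEG with stimulus-locked
    event-related components, 1/f background noise and injectable artifacts; a
    preprocessing chain (polyphase resampling, zero-phase Butterworth
    filtering, robust channel rejection, ICA-based artifact removal and
    statistical trial rejection); ERP averaging with a kernel-density tail
    test for significant peaks; a compact convolutional neural network for
    single-trial classification implemented with analytic gradients in C++;
    four training-data-composition scenarios (imagined-only, mixed,
    overt-only and multi-subject augmented) over three task types; and
    small-sample significance statistics (exact binomial chance thresholds,
    permutation nulls and Wilcoxon comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
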