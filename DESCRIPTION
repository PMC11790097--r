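Package: rlwbs
Title: Reinforcement-Learning Wavelet Base Selection for ECG Feature
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Adaptive, per-signal selection of the mother wavelet used for
    continuous-wavelet-transform (CWT) feature extraction from fixed-length
    multi-lead electrocardiogram (ECG) time series.  A stochastic policy
    network maps each raw signal to a probability distribution over an
    indexed catalog of 35 candidate wavelet bases (Haar, Daubechies,
    Symlet, Coiflet and spline-biorthogonal families) and is trained by
    REINFORCE policy gradient: every iteration a freshly re-initialised
    evaluation (backbone) classifier is trained on scalograms built with
    the sampled bases, its multi-label classification score on a held-out
    split is the reward, and the policy ascends the resulting gradient.
    Includes cascade-algorithm sampling of the mother wavelets, a sampled
    CWT, a full multi-label metric suite (precision, recall, sensitivity,
    specificity, F1, MCC, rank-based AUROC with macro/micro averaging), an
    energy-to-Shannon-entropy baseline selector, and a synthetic ECG
    generator whose class-discriminative morphology is wavelet-matched so
    that base-selection recovery is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
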