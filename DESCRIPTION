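Package: zerotrainbci
Title: Calibration-Free Unsupervised Decoding for Auditory ERP Spellers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised ("zero-training") decoding of event-related
    potential (ERP) brain-computer interface spellers. Implements a
    probabilistic linear decoder whose latent variable is the attended
    stimulus of a six-class auditory oddball trial, trained online by
    expectation maximization on unlabeled trials, with sign-flipped
    classifier pairs selected by data log-likelihood and posthoc
    re-analysis of past decisions. Ships a synthetic multichannel EEG
    session generator with the AMUSE trial structure (6 stimuli x 15
    iterations, 175 ms stimulus onset asynchrony), the online
    preprocessing chain (causal Chebyshev low-pass, epoching, baseline
    correction, variance-based outlier rejection, interval-mean features,
    per-trial normalization), a supervised shrinkage-regularized linear
    discriminant analysis baseline, and evaluation harnesses for
    selection/symbol accuracy, warm-up dynamics, signed-scaled AUC maps
    and extended-session simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
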