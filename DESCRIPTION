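Package: hyenalm
Title: Subquadratic Protein Language Models with the Hyena Operator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Character-level autoregressive protein language modeling built on
    the Hyena operator: implicit long convolutions realized as causal FFT
    convolutions, alternated with element-wise gating, as a subquadratic
    replacement for self-attention. Provides the full desk-scale pipeline:
    amino-acid tokenization, a two-block Hyena language model with an exact
    Toeplitz-matrix reference path, causal self-attention and dilated residual
    CNN baselines, autoregressive pretraining with Adam and cosine learning-rate
    decay, perplexity evaluation against Markov-chain entropy-rate oracles,
    fine-tuning heads for residue- and protein-level classification and
    regression, a metric suite (MCC, macro-F1, AUROC, AUPRC, Spearman,
    Student-t loss), and seeded synthetic corpus and task generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
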