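---
title: "Subquadratic protein language modeling with the Hyena operator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subquadratic protein language modeling with the Hyena operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyenalm)
```

## The model

Protein language models treat amino-acid sequences as sentences over a
25-character alphabet and learn their statistics by self-supervision. The
dominant architecture, the attention decoder, pays O(L^2) in time and memory
for a sequence of length L. This package implements a subquadratic
alternative built on the **Hyena operator**, which replaces attention with an
order-N recurrence of two cheap primitives:

* **long convolutions** — causal convolutions whose filters span the whole
  sequence, applied as lower-triangular Toeplitz matrices
  `(T_h)_ij = h(i-j)` but evaluated with FFTs in O(L log L);
* **element-wise gating** — multiplication by projected input streams,
  equivalent to diagonal matrices `D_x` acting on positions.

For order N = 2 the operator applied to the value stream `v` is

```
y = D_x2 · T_h2 · D_x1 · T_h1 · v,
```

where `v, x1, x2` are produced from the block input by one dense projection
followed by a depthwise causal short convolution. The long filters are
*implicit*: a small network of the time index (sinusoidal positional
features, two sine-activated hidden layers, a linear map to N·D channels,
modulated by a fixed exponential decay window) emits the taps `h(0..L-1)`,
so the number of learnable scalars does not grow with L.

The full language model is a standard pre-norm residual decoder: token
embedding, two blocks of (layer norm → mixer → residual, layer norm →
GELU feed-forward → residual), a final layer norm, and a decoding head tied
to the embedding table. The default configuration (2 blocks, embedding width
256, feed-forward width 1024, order 2, vocabulary 28, maximum length 1024)
has about 1.6 million trainable parameters:

```{r params}
m <- build_model(hyena_lm_config(), seed = 1)
count_parameters(m)
param_millions(m)
```

Two reference baselines share the tokenizer, block layout and training loop:
a causal multi-head attention decoder in two sizes ("tiny" matches the Hyena
model's 1.6 M budget; "base" has 8 layers at width 512, about 25.2 M), and
a 35-block dilated residual CNN regressor (about 41 M) for the
fluorescence-style regression comparison.

## Tokenization

Each amino acid is one token: the 20 standard residues in a fixed order
(D, N, E, K, V, Y, A, Q, M, I, T, L, R, F, G, C, S, P, H, W → ids 0–19),
five extended IUPAC codes for rare or ambiguous residues (X, B, Z, U, O →
ids 20–24), and pad/sep/unk specials (ids 25–27). Input is upper-cased;
characters outside the 25 residue codes map to unk. Overlong sequences are
truncated with a warning during pretraining and rejected during
fine-tuning.

## Training objective and metrics

Pretraining is autoregressive: the model maximizes
`∏ P(a_i | a_1..a_(i-1))` over tokens, i.e. minimizes the mean negative log
conditional probability H (nats per predicted position; position i's logits
predict token i+1, pads are masked out). Model quality is reported as
perplexity `PPL = exp(H)`: 1 for a perfect predictor, 20 for a model that
is effectively choosing uniformly among the 20 standard residues. The
optimizer is Adam (β1 = 0.9, β2 = 0.999, ε = 1e-8, no weight decay) with
initial learning rate 6e-4, cosine decay, optional linear warmup, global
gradient-norm clipping at 1, and length-bucketed right-padded batches.

Fine-tuning attaches a fresh linear decoder to the final-layer embeddings:
per position for residue-level tasks, or after masked mean pooling for
protein-level tasks (`n_classes = 1` with a raw scalar output for
regression). The backbone is updated by default; `freeze_backbone = TRUE`
gives the frozen-feature variant. Regression targets are standardized
internally during optimization and predictions mapped back, which changes
neither rank metrics nor the reported error scales' meaning. Downstream
metrics follow the task type: accuracy, macro-F1, MCC and AUROC for binary
tasks (plus macro AUROC/AUPRC one-vs-rest for multiclass), and Spearman
correlation, MSE, MAE and a Student-t loss for regression.

Two metric conventions deserve note. MCC returns 0 whenever a factor of its
denominator vanishes (a degenerate predictor carries no correlation). The
Student-t loss is not printed in full anywhere we could adopt it from, so
this package defines it as the mean negative log-kernel of a standardized
Student-t applied to residuals, `mean(((ν+1)/2)·log(1 + r²/ν))` with
configurable ν (default 1) — a heavy-tailed, logarithmically growing
alternative to MSE. Both conventions are deliberate interpretations.

## Synthetic data as ground truth

Real pretraining corpora and benchmark datasets are out of scope at desk
scale, so every pipeline stage is exercised on seeded generators with known
answers:

* **Markov proteomes** (`markov_source()`, `markov_proteome()`): first-order
  chains over the 20 standard residues whose exact entropy rate
  `H* = -Σ_s π(s) Σ_t P(s,t) log P(s,t)` is computed from the chain, so
  `exp(H*)` lower-bounds any model's held-out perplexity. A language model
  trained on such a corpus should approach — and can never beat — this
  bound, which turns pretraining into a testable estimation problem.
* **Motif tasks** (`motif_task()`): positives carry one degenerate
  position-weight motif (default length 8, consensus probability 0.9)
  implanted at a random interior position; class imbalance is configurable
  and mirrors the benchmark family this emulates (≈3:7 cleavage-style,
  ≈2:8 signal-peptide-style, balanced, and near-degenerate ≥99:1
  disorder-style presets). The consensus probability was calibrated once so
  that a converged small model reaches AUROC ≈ 0.95 — learnable but not
  trivially separable — and is not revisited per run.
* **Epistatic landscapes** (`landscape_model()`, `landscape_task()`): an
  additive-plus-pairwise fitness model around a random parent sequence
  (default length 60, baseline 4.4, additive effects N(-0.4, 0.3²) per
  site/residue, 30 epistatic site pairs with N(0, 0.3²) interactions,
  observation noise 0.1; scales calibrated once so the stated
  generalization targets are achievable by a converged small model). Training mutants lie at Hamming distance 1–3,
  test mutants at 4–10, so the deleterious additive bias shifts the test
  label distribution downward — a controlled analog of the
  train-close/test-far generalization probes used for fluorescence and
  stability landscapes.

What these generators do **not** emulate: family structure and phylogenetic
redundancy of real protein databases, realistic residue composition or
long-range contact statistics, and any biophysics behind real fluorescence or
stability labels. Passing the synthetic suites therefore demonstrates that
the architecture, training loop and metrics are implemented correctly and
can extract the statistical signal they are pointed at — not that the model
attains any particular accuracy on real proteins.

## Numerical choices

* All computation is double precision; heavy kernels (FFT convolution,
  depthwise short convolution, layer norm, GELU) are compiled (Rcpp +
  Armadillo) with hand-derived backward passes, verified against central
  finite differences for every parameter tensor of both architectures.
* The causal FFT convolution zero-pads to a highly composite length
  ≥ 2L-1 (factors 2, 3, 5), which realizes exact linear convolution and is
  measurably faster in this FFT implementation than padding to a power of
  two; agreement with the explicit O(L²) Toeplitz reference is part of the
  acceptance suite (relative error well under 1e-5).
* The filter network uses 8 sinusoidal time features, two hidden layers of
  width 32 with sine activation (frequency scale 8), and per-channel
  exponential decay rates log-spaced in [0.5, 8] over normalized time.
  The short convolution has width 3, causal left padding, identity-plus-
  noise initialization.
* Attention uses scaled scores (1/√d_head), a strict causal mask, and
  parameter-free rotary position embeddings — a learned position table
  would push the "base" configuration visibly past its printed parameter
  budget, and the Hyena model needs no position table because its filters
  are functions of the time index.
* Layer norm uses ε = 1e-5; weight initialization is N(0, 0.02²) for dense
  maps and 1/√fan-in for the filter network; the degenerate L = 1
  convolution path is evaluated analytically.
* Fine-tuning applies a discriminative learning rate: the fresh linear
  head trains at a multiple (default 30x) of the backbone rate. The
  mean-pooled representation of a layer-normalized backbone has small
  per-feature scale, so the decoder needs weights far larger than any
  backbone tensor's; without the multiplier the head cannot reach them
  within a desk-scale step budget and protein-level fine-tuning stalls at
  chance. Regression targets are standardized during optimization for the
  same reason.
* Protein-level fine-tuning starts from a backbone pretrained on the task
  corpus. With dense per-residue supervision a random backbone trains
  fine, but a single pooled label per sequence is too weak a signal to
  shape features from scratch at these sizes — pretraining first is both
  the methodologically faithful pipeline and the one that works.
* Reported training runs are deterministic given the seed: initialization,
  validation split, batch order and every stochastic generator run off a
  single seeded RNG stream.

## Design decisions on open points

The architecture source material names components without fully pinning
them; the following were decided once and hold throughout:

* **Block order**: pre-normalization, as is standard for this model
  family; the decoding "MLP" head is realized as the final layer norm plus
  the (tied) linear map — the smallest reading consistent with the 1.6 M
  budget.
* **Filter conditioning**: filters depend on the time index only. A
  data-conditioned filter would contradict the Toeplitz formulation
  `(T_h)_ij = h(i-j)`, which is the formulation everything here is tested
  against.
* **Cross-entropy normalization**: the average runs over predicted
  positions (2..L with no beginning-of-sequence token), the only reading
  that makes PPL = e^H consistent.
* **No sequence packing**: batches are padded, never packed across
  sequence boundaries, so no position ever conditions on a different
  record; the sep token is reserved but unused.
* **Fine-tuning hyperparameters** (learning rate, epochs, early-stopping
  patience) are configurable defaults, not claims about any original
  training run.

## Problem sizes in the shipped checks

The test suite and the acceptance script run everything at desk scale,
chosen so the full pipeline — generation, pretraining, evaluation,
fine-tuning — completes on a single CPU core in minutes: entropy-rate
recovery pretrains a width-64 model on 5,000 Markov sequences of length
40–100 for 1,200 steps at batch 16 (the in-suite variant uses 800 steps);
the architecture comparison trains a ~49k-parameter Hyena model against a
~46k-parameter attention decoder for 500 steps on a shared 2,500-sequence
corpus; the fine-tuning checks use 2,500 (protein motif), 700 (residue
motif) and 2,500 (landscape) sequences. These sizes are statements about
what suffices to demonstrate correctness, not about the limits of the
implementation.

## Known limitations

* Pure-CPU training: no GPU path, no mixed precision, no multi-device
  support; wall-clock and memory benchmarking of the subquadratic claim is
  out of scope.
* The CNN baseline implements forward evaluation and parameter accounting
  only; it is a parameter-count and smoke-test reference, not a trained
  competitor.
* Sampling/generation utilities are limited to what the tests need.
* The synthetic generators make no attempt to mimic real protein family
  structure; see above for what passing tests does and does not show.
```
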