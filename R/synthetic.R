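#' Markov-chain sequence source
#'
#' A first-order Markov chain over the 20 standard amino-acid tokens (or any
#' supplied state set) with a known, exactly computable entropy rate. The
#' entropy rate H* (nats/symbol) lower-bounds the cross-entropy any model can
#' achieve on held-out sequences from the source, so `exp(H*)` is the
#' optimal-perplexity oracle used in the pretraining tests.
#'
#' @param transition Row-stochastic transition matrix (rows sum to 1). For a
#'   memoryless source pass a matrix with identical rows.
#' @param states Character vector of state symbols (defaults to the 20
#'   standard amino acids when the matrix is 20 x 20).
#' @param init Initial distribution (defaults to the stationary
#'   distribution).
#' @return A `markov_source` list with `transition`, `states`, `stationary`,
#'   `entropy_rate` and `init`.
#' @export
markov_source <- function(transition, states = NULL, init = NULL) {
  transition <- as.matrix(transition)
  if (nrow(transition) != ncol(transition)) stop("transition must be square")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition rows must be nonnegative and sum to 1")
  if (is.null(states)) {
    states <- if (nrow(transition) == 20L) build_vocabulary()$standard_tokens
              else as.character(seq_len(nrow(transition)))
  }
  stopifnot(length(states) == nrow(transition))
  if (!.is_irreducible(transition)) stop("transition chain is reducible")
  pi_s <- .stationary_dist(transition)
  src <- list(transition = transition, states = states, stationary = pi_s,
              init = if (is.null(init)) pi_s else init)
  src$entropy_rate <- .entropy_rate_exact(transition, pi_s)
  class(src) <- "markov_source"
  src
}

.is_irreducible <- function(P) {
  n <- nrow(P)
  A <- P > 0
  R <- A | diag(TRUE, n)
  for (i in seq_len(ceiling(log2(n)) + 1L)) R <- (R %*% R) > 0
  all(R)
}

.stationary_dist <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

.entropy_rate_exact <- function(P, pi_s) {
  lp <- ifelse(P > 0, log(P), 0)
  -sum(pi_s * rowSums(P * lp))
}

#' Exact entropy rate of a Markov source
#'
#' `H* = -sum_s pi(s) sum_t P(s,t) log P(s,t)` in nats per symbol, with the
#' stationary distribution pi computed from the chain.
#'
#' @param source A [markov_source()].
#' @return Entropy rate in nats/symbol.
#' @examples
#' entropy_rate(uniform_source())  # log(20)
#' @export
entropy_rate <- function(source) {
  stopifnot(inherits(source, "markov_source"))
  source$entropy_rate
}

#' Memoryless uniform source over the 20 standard amino acids
#' @return A `markov_source` with entropy rate log(20).
#' @export
uniform_source <- function() {
  markov_source(matrix(1 / 20, 20, 20))
}

#' Random sparse first-order source
#'
#' Rows drawn from a symmetric Dirichlet; small concentrations give strongly
#' structured (low-entropy) chains. Each row receives a small floor so the
#' chain is irreducible.
#'
#' @param concentration Dirichlet concentration per entry (default 0.1).
#' @param n_states Number of states (default 20, the standard amino acids).
#' @param seed Integer seed.
#' @return A `markov_source`.
#' @export
random_markov_source <- function(concentration = 0.1, n_states = 20L,
                                 seed = 1L) {
  rng <- .local_rng(seed)
  G <- matrix(rng$vec(n_states * n_states, sd = 1), n_states, n_states)
  # gamma draws via inverse-free construction: use rgamma under managed state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  P <- matrix(stats::rgamma(n_states * n_states, shape = concentration),
              n_states, n_states)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  P <- P + 1e-4
  P <- P / rowSums(P)
  markov_source(P)
}

#' Sample a synthetic proteome from a Markov source
#'
#' Seeded and bit-reproducible: the same (source, n, length range, seed)
#' yields identical records (and identical FASTA bytes when written).
#'
#' @param source A [markov_source()].
#' @param n Number of sequences.
#' @param length_range Integer range c(min, max); lengths drawn uniformly.
#' @param seed Integer seed.
#' @param fasta Optional path; when given, records are written as FASTA and
#'   a JSON sidecar `<path>.json` stores the ground-truth entropy rate.
#' @return A list with `records` (data.frame id/sequence), `entropy_rate`
#'   (H*, nats/symbol) and `optimal_ppl` (`exp(H*)`).
#' @export
markov_proteome <- function(source, n, length_range = c(50L, 300L), seed = 1L,
                            fasta = NULL) {
  stopifnot(inherits(source, "markov_source"), n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  S <- length(source$states)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    ids <- integer(L)
    ids[1] <- sample.int(S, 1L, prob = source$init)
    if (L > 1L) for (t in 2:L) {
      ids[t] <- sample.int(S, 1L, prob = source$transition[ids[t - 1L], ])
    }
    seqs[i] <- paste(source$states[ids], collapse = "")
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  records <- data.frame(id = sprintf("synth_%05d", seq_len(n)),
                        sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    write_fasta(records, fasta)
    jsonlite::write_json(list(entropy_rate = source$entropy_rate,
                              optimal_ppl = exp(source$entropy_rate),
                              n = n, seed = seed),
                         paste0(fasta, ".json"), auto_unbox = TRUE, digits = NA)
  }
  list(records = records, entropy_rate = source$entropy_rate,
       optimal_ppl = exp(source$entropy_rate))
}

# ---- motif tasks ------------------------------------------------------------

#' Specification of a degenerate sequence motif
#'
#' A position-weight pattern: at each motif position the consensus residue
#' appears with probability `consensus_prob`, otherwise a residue is drawn
#' uniformly from the remaining standard amino acids. Degeneracy keeps the
#' classification task learnable but not trivially separable.
#'
#' @param length Motif length (default 8).
#' @param consensus_prob Per-position consensus probability (default 0.9,
#'   calibrated once so a converged small model reaches AUROC about 0.95).
#' @param seed Seed for drawing the consensus residues.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(length = 8L, consensus_prob = 0.9, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 7717L)
  std <- build_vocabulary()$standard_tokens
  consensus <- sample(std, length, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(length = as.integer(length), consensus = consensus,
                 consensus_prob = consensus_prob),
            class = "motif_spec")
}

#' Synthetic motif classification task
#'
#' Positive sequences carry one implanted degenerate motif at a random
#' interior position; negatives are pure background. Emulates binary protein
#' property tasks at configurable class imbalance: presets mirror the
#' neuropeptide-cleavage (~3:7), signal-peptide (~2:8), balanced-solubility
#' and near-degenerate disorder label ratios. At `resolution = "protein"` the
#' label is per-sequence; at `"residue"` the label string marks in-motif
#' positions with `1`.
#'
#' @param n Number of sequences.
#' @param motif A [motif_spec()].
#' @param class_ratio Fraction of positive sequences, in (0, 1). The
#'   realized count is `round(class_ratio * n)`.
#' @param resolution `"protein"` or `"residue"`.
#' @param length_range Sequence length range.
#' @param seed Integer seed.
#' @param splits Named fractions for train/valid/test (must sum to 1).
#' @return A `task_dataset` data.frame with columns `sequence`,
#'   `label` (protein) or `labels` (residue), and `split`.
#' @export
motif_task <- function(n, motif = motif_spec(), class_ratio = 0.5,
                       resolution = c("protein", "residue"),
                       length_range = c(50L, 120L), seed = 1L,
                       splits = c(train = 0.7, valid = 0.1, test = 0.2)) {
  resolution <- match.arg(resolution)
  if (class_ratio <= 0 || class_ratio >= 1) stop("class_ratio must be in (0,1)")
  n_pos <- round(class_ratio * n)
  if (n_pos == 0L || n_pos == n) stop("class_ratio unachievable at n = ", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  std <- build_vocabulary()$standard_tokens
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  is_pos <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  seqs <- character(n); lab_str <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    chars <- sample(std, L, replace = TRUE)
    marks <- rep("0", L)
    if (is_pos[i] == 1L) {
      m <- motif$length
      start <- sample.int(L - m + 1L, 1L)
      core <- ifelse(stats::runif(m) < motif$consensus_prob,
                     motif$consensus, sample(std, m, replace = TRUE))
      chars[start:(start + m - 1L)] <- core
      marks[start:(start + m - 1L)] <- "1"
    }
    seqs[i] <- paste(chars, collapse = "")
    lab_str[i] <- paste(marks, collapse = "")
  }
  split <- sample(rep(names(splits), round(splits * n))[seq_len(n)])
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  df <- if (resolution == "protein") {
    data.frame(sequence = seqs, label = is_pos, split = split,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sequence = seqs, labels = lab_str, split = split,
               stringsAsFactors = FALSE)
  }
  attr(df, "task_spec") <- task_spec(
    task_type = "binary", resolution = resolution, n_classes = 2L)
  class(df) <- c("task_dataset", "data.frame")
  df
}

# ---- epistatic fitness landscape --------------------------------------------

#' Synthetic epistatic fitness landscape
#'
#' An additive-plus-pairwise model of a mutational landscape around a parent
#' sequence: each (site, residue) substitution carries an additive effect,
#' a configurable number of random site pairs carry epistatic interaction
#' terms active when both sites are mutated, and observations add Gaussian
#' noise. Additive effects have a deleterious bias, so label distributions
#' shift downward with mutation distance — training on close mutants
#' (Hamming distance 1-3) and testing on distant ones (4+) therefore probes
#' generalization under distribution shift.
#'
#' @param parent_length Length of the parent sequence (default 60).
#' @param baseline Label of the parent sequence (default 4.4).
#' @param additive_mean,additive_sd Moments of the per-(site,residue)
#'   additive effects (defaults -0.4, 0.3).
#' @param n_epistatic Number of interacting site pairs (default 30).
#' @param epistatic_sd Scale of the pairwise terms (default 0.3).
#' @param noise_sd Observation noise (default 0.1).
#' @param seed Integer seed.
#' @return A `landscape_model` list.
#' @export
landscape_model <- function(parent_length = 60L, baseline = 4.4,
                            additive_mean = -0.4, additive_sd = 0.3,
                            n_epistatic = 30L, epistatic_sd = 0.3,
                            noise_sd = 0.1, seed = 1L) {
  stopifnot(parent_length >= 20L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 3391L)
  std <- build_vocabulary()$standard_tokens
  parent <- sample(std, parent_length, replace = TRUE)
  additive <- matrix(stats::rnorm(parent_length * 20, additive_mean, additive_sd),
                     parent_length, 20, dimnames = list(NULL, std))
  pairs <- if (n_epistatic > 0L) {
    t(replicate(n_epistatic, sample.int(parent_length, 2L)))
  } else matrix(integer(0), 0L, 2L)
  ecoef <- stats::rnorm(n_epistatic, 0, epistatic_sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(parent = parent, baseline = baseline, additive = additive,
                 pairs = pairs, ecoef = ecoef, noise_sd = noise_sd),
            class = "landscape_model")
}

#' Noise-free landscape label of a mutant
#' @param model A [landscape_model()].
#' @param chars Character vector of residues (same length as the parent).
#' @return Numeric label: baseline + additive + epistatic terms.
#' @export
landscape_label <- function(model, chars) {
  mut <- which(chars != model$parent)
  y <- model$baseline
  if (length(mut) > 0) {
    y <- y + sum(model$additive[cbind(mut, match(chars[mut], colnames(model$additive)))])
    both <- (model$parent[model$pairs[, 1]] != chars[model$pairs[, 1]]) &
            (model$parent[model$pairs[, 2]] != chars[model$pairs[, 2]])
    y <- y + sum(model$ecoef[both])
  }
  y
}

#' Mutation-distance-split regression task from a landscape
#'
#' Train split: mutants at Hamming distance 1-3 from the parent. Test split:
#' distance 4 up to `max_test_distance`. Labels are the landscape value plus
#' Gaussian noise. Because additive effects are deleterious on average, the
#' two splits' label means differ — an intentional distribution shift.
#'
#' @param model A [landscape_model()].
#' @param n_train,n_test Sequences per split (a tenth of the train split is
#'   tagged `valid`).
#' @param max_test_distance Largest test Hamming distance (default 10).
#' @param seed Integer seed.
#' @return A `task_dataset` data.frame: `sequence`, `label`, `split`,
#'   `distance`.
#' @export
landscape_task <- function(model, n_train = 2000L, n_test = 500L,
                           max_test_distance = 10L, seed = 1L) {
  stopifnot(inherits(model, "landscape_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  std <- build_vocabulary()$standard_tokens
  Lp <- length(model$parent)
  make <- function(n, dmin, dmax) {
    dists <- sample(dmin:dmax, n, replace = TRUE)
    seqs <- character(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      chars <- model$parent
      sites <- sample.int(Lp, dists[i])
      for (s in sites) {
        chars[s] <- sample(setdiff(std, model$parent[s]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
      ys[i] <- landscape_label(model, chars) + stats::rnorm(1, 0, model$noise_sd)
    }
    data.frame(sequence = seqs, label = ys, distance = dists,
               stringsAsFactors = FALSE)
  }
  tr <- make(n_train, 1L, 3L)
  te <- make(n_test, 4L, max_test_distance)
  tr$split <- sample(rep(c("train", "valid"),
                         c(n_train - round(0.1 * n_train), round(0.1 * n_train))))
  te$split <- "test"
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  df <- rbind(tr, te)
  attr(df, "task_spec") <- task_spec(task_type = "regression",
                                     resolution = "protein", n_classes = 1L)
  class(df) <- c("task_dataset", "data.frame")
  df
}
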