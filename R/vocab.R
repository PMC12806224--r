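#' Amino-acid vocabulary
#'
#' The model works on a fixed 28-token character vocabulary: the 20 standard
#' amino acids, five extended IUPAC codes for rare or ambiguous residues
#' (X, B, Z, U, O), and three special tokens (pad, sep, unk). Standard tokens
#' occupy ids 0..19 in a fixed order, rare tokens 20..24, specials 25..27.
#' Token ids are 0-based everywhere in the public interface.
#'
#' @return An object of class `aa_vocab`: a list with `standard_tokens`,
#'   `rare_tokens`, `special_tokens` (named character vector with entries
#'   `pad`, `sep`, `unk`), `tokens` (all 28 characters in id order), `size`,
#'   and the special-token ids `pad_id`, `sep_id`, `unk_id`.
#' @examples
#' v <- build_vocabulary()
#' v$size            # 28
#' token_id(v, "D")  # 0
#' @export
build_vocabulary <- function() {
  standard <- c("D", "N", "E", "K", "V", "Y", "A", "Q", "M", "I",
                "T", "L", "R", "F", "G", "C", "S", "P", "H", "W")
  rare <- c("X", "B", "Z", "U", "O")
  special <- c(pad = "-", sep = "|", unk = "?")
  tokens <- c(standard, rare, unname(special))
  stopifnot(length(standard) == 20L, length(rare) == 5L,
            !anyDuplicated(tokens))
  v <- list(
    standard_tokens = standard,
    rare_tokens = rare,
    special_tokens = special,
    tokens = tokens,
    size = length(tokens),
    pad_id = 25L,
    sep_id = 26L,
    unk_id = 27L
  )
  class(v) <- "aa_vocab"
  v
}

#' Look up token ids by character
#'
#' @param vocab An `aa_vocab`.
#' @param chars Character vector of single-character tokens.
#' @return Integer 0-based ids; `NA` for characters outside the vocabulary.
#' @export
token_id <- function(vocab, chars) {
  match(chars, vocab$tokens) - 1L
}

#' Encode an amino-acid string as token ids
#'
#' One token per character. Input is upper-cased first, so lower-case FASTA
#' dialects are accepted. Characters outside the 25 amino-acid codes map to
#' the unk token. Length is preserved.
#'
#' @param sequence Nonempty character scalar.
#' @param vocab An `aa_vocab` (defaults to [build_vocabulary()]).
#' @return Integer vector of 0-based token ids, class `token_seq`.
#' @examples
#' encode("DNE")  # 0 1 2
#' @export
encode <- function(sequence, vocab = build_vocabulary()) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a nonempty character scalar")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ids <- match(chars, vocab$tokens[1:25]) - 1L
  ids[is.na(ids)] <- vocab$unk_id
  structure(ids, class = "token_seq")
}

#' Decode token ids back to an amino-acid string
#'
#' Inverse of [encode()] on amino-acid tokens; special tokens render as their
#' sentinel characters (`-`, `|`, `?` by default).
#'
#' @param tokens Nonempty integer vector of valid 0-based ids.
#' @param vocab An `aa_vocab`.
#' @return Character scalar.
#' @export
decode <- function(tokens, vocab = build_vocabulary()) {
  tokens <- as.integer(tokens)
  if (length(tokens) == 0L) stop("`tokens` must be nonempty")
  if (anyNA(tokens) || any(tokens < 0L) || any(tokens >= vocab$size)) {
    stop("token ids must lie in [0, ", vocab$size, ")")
  }
  paste(vocab$tokens[tokens + 1L], collapse = "")
}

#' Encode a batch of sequences into a padded time-major id matrix
#'
#' Internal work-horse for training: right-pads with the pad token and
#' truncates (with a warning) or rejects overlong input.
#'
#' @param seqs Character vector of sequences.
#' @param vocab An `aa_vocab`.
#' @param max_len Maximum allowed length.
#' @param overflow `"truncate"` (pretraining) or `"error"` (fine-tuning).
#' @return List with `ids` (L x B integer matrix, 0-based, pad-filled) and
#'   `lengths` (integer vector of true lengths).
#' @keywords internal
encode_batch <- function(seqs, vocab = build_vocabulary(), max_len = 1024L,
                         overflow = c("truncate", "error")) {
  overflow <- match.arg(overflow)
  enc <- lapply(seqs, encode, vocab = vocab)
  lens <- lengths(enc)
  if (any(lens > max_len)) {
    if (overflow == "error") {
      stop("sequence(s) longer than max_len = ", max_len, ": records ",
           paste(which(lens > max_len), collapse = ", "))
    }
    warning(sum(lens > max_len), " sequence(s) truncated to max_len = ",
            max_len)
    enc <- lapply(enc, function(x) x[seq_len(min(length(x), max_len))])
    lens <- lengths(enc)
  }
  L <- max(lens)
  ids <- matrix(vocab$pad_id, nrow = L, ncol = length(enc))
  for (b in seq_along(enc)) {
    if (lens[b] > 0L) ids[seq_len(lens[b]), b] <- enc[[b]]
  }
  list(ids = ids, lengths = lens)
}
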