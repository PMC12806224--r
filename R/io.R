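#' Read a FASTA file
#'
#' Handles wrapped or unwrapped lines, mixed case and CRLF endings; record
#' order is preserved. Duplicate record ids are kept, with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(first), ">"))
    stop("malformed FASTA at line 1: sequence data before the first header")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    warning("duplicate FASTA ids kept as-is: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = as.character(set), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data frame with `id` and `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records) %||% seq_along(records),
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a task TSV file
#'
#' Tab-separated, UTF-8, header required. Columns: `sequence` plus `label`
#' (protein-level scalar/class) or `labels` (residue-level digit string of
#' the same length as the sequence), and optionally `split`
#' (train/valid/test; rows default to `train` with a message when absent).
#' Malformed rows are rejected with their row number.
#'
#' @param path Path to the TSV.
#' @param spec A [task_spec()] the file must conform to.
#' @return A `task_dataset` data.frame.
#' @export
read_task_tsv <- function(path, spec) {
  stopifnot(inherits(spec, "task_spec"))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!"sequence" %in% names(df)) stop("task TSV needs a `sequence` column")
  if (spec$resolution == "protein") {
    if (!"label" %in% names(df)) stop("protein-level task TSV needs a `label` column")
    df$label <- if (spec$task_type == "regression") as.numeric(df$label)
                else as.integer(df$label)
    bad <- which(is.na(df$label))
    if (length(bad) > 0) stop("unparsable label at row ", bad[1])
    if (spec$task_type != "regression" &&
        any(df$label < 0 | df$label >= spec$n_classes))
      stop("label outside [0, ", spec$n_classes, ") at row ",
           which(df$label < 0 | df$label >= spec$n_classes)[1])
  } else {
    if (!"labels" %in% names(df)) stop("residue-level task TSV needs a `labels` column")
    bad <- which(nchar(df$labels) != nchar(df$sequence))
    if (length(bad) > 0)
      stop("residue labels length mismatch at row ", bad[1])
  }
  if (!"split" %in% names(df)) {
    message("no `split` column: all rows assigned to the train split")
    df$split <- "train"
  }
  attr(df, "task_spec") <- spec
  class(df) <- c("task_dataset", "data.frame")
  df
}

#' Write a task dataset as TSV
#' @param data A `task_dataset`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_task_tsv <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

.config_schema <- list(
  model = c("arch", "n_layers", "embed_dim", "ffn_dim", "order", "n_heads",
            "max_len", "vocab_size", "head_tied", "short_conv_width",
            "filter_features", "filter_hidden", "size"),
  train = c("batch_size", "max_len", "lr", "min_lr", "total_steps",
            "warmup_steps", "val_fraction", "eval_every", "clip_norm", "seed"),
  task = c("task_type", "resolution", "n_classes"),
  paths = c("fasta", "data", "out", "model"),
  seed = NULL
)

#' Read and validate a YAML run configuration
#'
#' Top-level sections `model`, `train`, `task`, `paths`, `seed`; unknown
#' sections or keys are rejected rather than silently ignored.
#'
#' @param path Path to a YAML file.
#' @return Validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad) > 0)
      stop("unknown key(s) in `", sec, "`: ", paste(bad, collapse = ", "))
  }
  cfg
}

# build a model_config from the `model` section of a run config
.model_config_from_list <- function(m) {
  if (!is.null(m$size)) return(attention_lm_config(m$size))
  args <- m[setdiff(names(m), "size")]
  do.call(model_config, args)
}

.train_config_from_list <- function(tr) {
  if (is.null(tr)) return(train_config())
  do.call(train_config, tr)
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file keyed container (R serialization) holding the full parameter
#' tree with its embedded config; the round trip is bit-exact.
#'
#' @param params A parameter tree (`protein_lm`, `task_model`, ...).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return The parameter tree.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
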