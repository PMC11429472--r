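# Checkpoint serialisation: a single-file archive holding the config, a
# version field, and every parameter value by name.

#' Save a model checkpoint
#'
#' @param model a `fundusseg_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(model$params, function(p) p$v)
  saveRDS(list(format = "fundusseg-checkpoint", version = model$version,
               cfg = model$cfg, values = values), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the model from the embedded config and restores all parameter
#' values.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `fundusseg_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fundusseg-checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  model <- build_model(ck$cfg, seed = 0L)
  if (!setequal(names(ck$values), names(model$params))) {
    stop("checkpoint parameters do not match the model configuration")
  }
  for (nm in names(ck$values)) model$params[[nm]]$v <- ck$values[[nm]]
  model
}

# Order-stable digest of the text encoder's behaviour: embeddings of both
# class prompts.  Used to verify the encoder is frozen across training.
text_encoder_fingerprint <- function(model) {
  unlist(lapply(seq_along(model$cfg$class_names) - 1L, function(ci) {
    model$text_encoder$encode(fill_prompt(model$cfg$template, ci))
  }))
}
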