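# Prompt construction and text embedding for the dynamic segmentation head.
#
# The lesion class predicted by the auxiliary classifier (or the ground-truth
# class during training, i.e. teacher forcing) is filled into a fixed English
# template; the sentence is embedded by a frozen text encoder and the
# embedding conditions the controller that generates the head's convolution
# parameters.  The default encoder is a deterministic hashing stub with the
# same 512-dimensional output a CLIP text encoder would give, so the whole
# pipeline runs offline; a real CLIP encoder can be plugged in through the
# same interface.

#' The prompt template and class names
#'
#' The template string is kept verbatim, including its grammar:
#' `"it is a image of {lesion class}"`.
#'
#' @param class_names ordered class names filled into the template.
#' @return list of class `prompt_template`.
#' @export
prompt_template <- function(class_names = c("benign tumor", "malignant tumor")) {
  structure(list(template = "it is a image of {lesion class}",
                 class_names = class_names),
            class = "prompt_template")
}

#' Fill the prompt template with a class
#'
#' @param template a [prompt_template()].
#' @param class_index zero-based class index (0 = first class name).
#' @return the prompt sentence, with no unexpanded placeholder.
#' @export
#' @examples
#' fill_prompt(prompt_template(), 0)  # "it is a image of benign tumor"
fill_prompt <- function(template, class_index) {
  stopifnot(inherits(template, "prompt_template"))
  if (!class_index %in% (seq_along(template$class_names) - 1L)) {
    stop("class_index out of range: ", class_index)
  }
  out <- sub("{lesion class}", template$class_names[class_index + 1L],
             template$template, fixed = TRUE)
  if (grepl("{", out, fixed = TRUE)) stop("unexpanded placeholder in prompt")
  out
}

# Stable 31-bit polynomial hash of a character string (process independent).
str_hash31 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  h
}

#' Deterministic hash-based text encoder
#'
#' Maps a sentence to a unit-norm vector seeded by a stable hash of its
#' lowercased token sequence.  Deterministic across processes and platforms;
#' distinct sentences get (almost surely) distinct directions.  Serves as the
#' frozen, parameter-free text encoder for fully offline training.
#'
#' @param sentence nonempty character scalar.
#' @param d embedding dimension (512, matching a CLIP text width).
#' @return numeric vector of length `d` with unit Euclidean norm.
#' @export
hash_text_encoder <- function(sentence, d = 512L) {
  stopifnot(is.character(sentence), length(sentence) == 1L, nzchar(sentence))
  toks <- strsplit(tolower(trimws(sentence)), "[[:space:]]+")[[1]]
  h <- 17
  for (i in seq_along(toks)) {
    h <- (h * 131 + i * str_hash31(toks[i])) %% 2147483647
  }
  v <- with_private_seed(as.integer(h), stats::rnorm(d))
  v / sqrt(sum(v * v))
}

#' Construct a text encoder behind the frozen-encoder interface
#'
#' @param type `"hash"` (default, offline) or `"clip"`.  The CLIP variant
#'   requires external weights and is not bundled; requesting it without a
#'   loader errors.
#' @param d embedding dimension.
#' @return list with `encode(sentence)`, `name`, `d` and `frozen = TRUE`.
#' @export
make_text_encoder <- function(type = c("hash", "clip"), d = 512L) {
  type <- match.arg(type)
  if (type == "clip") {
    stop("the CLIP text encoder requires externally supplied weights; ",
         "use type = 'hash' or plug in an encoder with the same interface")
  }
  list(encode = function(sentence) hash_text_encoder(sentence, d),
       name = "hash", d = as.integer(d), frozen = TRUE)
}
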