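# Weight initialisation and the AdamW optimiser.

#' @keywords internal
trunc_normal <- function(n, sd = 0.02, lim = 2) {
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > lim * sd)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

init_linear <- function(ci, co, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (ci + co))
  matrix(trunc_normal(ci * co, sd = sd), ci, co)
}

#' AdamW optimiser with decoupled weight decay
#'
#' @param params list of parameter nodes (from [ag_param()]).
#' @param lr learning rate.
#' @param betas first/second moment decay rates.
#' @param eps numerical stabiliser.
#' @param weight_decay decoupled decay, applied only to parameters with more
#'   than one dimension (biases and normalisation gains are exempt, the usual
#'   convention).
#' @return an optimiser object with `$step()`, `$zero_grad()` and `$lr` field.
#' @keywords internal
adamw <- function(params, lr = 2e-4, betas = c(0.9, 0.999), eps = 1e-8,
                  weight_decay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v2 <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  decayed <- vapply(params, function(p) {
    d <- dim(p$v)
    !is.null(d) && length(d) >= 2L && all(d > 1L)
  }, logical(1))
  st$step <- function() {
    st$t <- st$t + 1L
    b1 <- betas[1]; b2 <- betas[2]
    c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
    for (i in seq_along(st$params)) {
      p <- st$params[[i]]
      if (is.null(p$g)) next
      g <- p$g
      st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
      st$v2[[i]] <- b2 * st$v2[[i]] + (1 - b2) * g * g
      upd <- (st$m[[i]] / c1) / (sqrt(st$v2[[i]] / c2) + eps)
      if (decayed[i]) upd <- upd + weight_decay * p$v
      p$v <- p$v - st$lr * upd
    }
    invisible(NULL)
  }
  st$zero_grad <- function() ag_zero_grad(st$params)
  st
}
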