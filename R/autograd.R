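# Reverse-mode automatic differentiation on a define-by-run tape.
#
# Values are plain numeric matrices/arrays.  A node is an environment holding
# the forward value (`v`), an accumulated gradient (`g`), its parent nodes and
# a backward closure mapping the output gradient to one gradient per parent.
# Ops append their node to the active tape; `ag_backward()` walks the tape in
# reverse (append order is already topological).  When gradients are globally
# disabled, or no input requires a gradient, ops return plain values so that
# evaluation costs no tape memory.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$grad_on <- TRUE

is_node <- function(x) inherits(x, "agnode")

#' @keywords internal
val <- function(x) if (is_node(x)) x$v else x

node_req <- function(x) is_node(x) && isTRUE(x$req)

#' Create a trainable parameter node
#'
#' @param v numeric array holding the initial value.
#' @param name optional label used in checkpoints and debugging.
#' @return an `agnode` environment with `req = TRUE`.
#' @keywords internal
ag_param <- function(v, name = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$parents <- list()
  n$bw <- NULL
  n$req <- TRUE
  n$name <- name
  class(n) <- "agnode"
  n
}

# Constant node (never tracked); plain values work everywhere, so this is
# rarely needed.
ag_const <- function(v) v

# Wrap an op result: record on the tape only when some input needs gradients.
ag_op <- function(value, inputs, backward) {
  if (!.ag$grad_on) return(value)
  if (!any(vapply(inputs, node_req, logical(1)))) return(value)
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$parents <- inputs
  n$bw <- backward
  n$req <- TRUE
  class(n) <- "agnode"
  tp <- .ag$tape
  if (is.null(tp)) {
    tp <- new.env(parent = emptyenv())
    tp$nodes <- vector("list", 256L)
    tp$n <- 0L
    .ag$tape <- tp
  }
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- n
  n
}

#' Evaluate an expression without recording gradients
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_on
  .ag$grad_on <- FALSE
  on.exit(.ag$grad_on <- old)
  expr
}

# Reset the tape (called at the start of each training step).
ag_tape_reset <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into every parameter node reachable from `loss`.
#' The tape is cleared afterwards.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$v) == 1L)
  tp <- .ag$tape
  loss$g <- 1
  if (!is.null(tp) && tp$n > 0L) {
    for (i in seq(tp$n, 1L)) {
      nd <- tp$nodes[[i]]
      if (is.null(nd$g)) next
      gs <- nd$bw(nd$g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        if (node_req(p) && !is.null(gs[[j]])) {
          p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
        }
      }
      nd$g <- NULL          # free intermediate gradients eagerly
      tp$nodes[[i]] <- NULL # drop the reference so values can be collected
    }
  }
  ag_tape_reset()
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- elementwise and linear-algebra ops -------------------------------------

ag_add <- function(a, b) {
  ag_op(val(a) + val(b), list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_op(val(a) - val(b), list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a constant (no gradient into `k`)
ag_mulc <- function(a, k) {
  ag_op(val(a) * k, list(a), function(g) list(g * k))
}

ag_addc <- function(a, k) {
  ag_op(val(a) + k, list(a), function(g) list(g))
}

ag_neg <- function(a) ag_mulc(a, -1)

# scalar / scalar division, both differentiable
ag_sdiv <- function(a, b) {
  av <- val(a); bv <- val(b)
  ag_op(av / bv, list(a, b),
        function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ag_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# x [n, ci] %*% W [ci, co] + b [co]
ag_linear <- function(x, W, b = NULL) {
  xv <- val(x); Wv <- val(W)
  out <- xv %*% Wv
  if (!is.null(b)) out <- out + rep(val(b), each = nrow(out))
  ins <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, ins, function(g) {
    gx <- g %*% t(Wv)
    gW <- crossprod(xv, g)
    if (is.null(b)) list(gx, gW) else list(gx, gW, colSums(g))
  })
}

ag_relu <- function(x) {
  xv <- val(x)
  m <- xv > 0
  ag_op(xv * m, list(x), function(g) list(g * m))
}

# exact GELU: x * Phi(x)
ag_gelu <- function(x) {
  xv <- val(x)
  ph <- stats::pnorm(xv)
  ag_op(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-val(x)))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_sum <- function(x) {
  xv <- val(x)
  ag_op(sum(xv), list(x), function(g) list(array(g, dim(xv) %||% length(xv))))
}

ag_mean <- function(x) {
  xv <- val(x)
  n <- length(xv)
  ag_op(sum(xv) / n, list(x), function(g) list(array(g / n, dim(xv) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gather rows; idx may contain NA meaning "a row of zeros" (used for padding).
ag_rows <- function(x, idx) {
  xv <- val(x)
  nc <- ncol(xv)
  nas <- which(is.na(idx))
  idx0 <- idx
  if (length(nas)) idx0[nas] <- 1L
  out <- xv[idx0, , drop = FALSE]
  if (length(nas)) out[nas, ] <- 0
  ag_op(out, list(x), function(g) {
    ok <- if (length(nas)) -nas else TRUE
    acc <- rowsum(g[ok, , drop = FALSE],
                  group = idx0[ok], reorder = FALSE)
    gx <- matrix(0, nrow(xv), nc)
    gx[as.integer(rownames(acc)), ] <- acc
    list(gx)
  })
}

# Row-wise softmax over a matrix.
ag_softmax_rows <- function(x) {
  xv <- val(x)
  m <- xv - apply(xv, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ag_op(s, list(x), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Layer normalisation across columns (channels), per row.
ag_layernorm <- function(x, gamma, beta, eps = 1e-6) {
  xv <- val(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- val(gamma); bv <- val(beta)
  out <- xhat * rep(gv, each = nrow(xv)) + rep(bv, each = nrow(xv))
  ag_op(out, list(x, gamma, beta), function(g) {
    gh <- g * rep(gv, each = nrow(g))
    gx <- inv * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    list(gx, colSums(g * xhat), colSums(g))
  })
}

# Concatenate matrices column-wise.
ag_cbind <- function(...) {
  ins <- list(...)
  vals <- lapply(ins, val)
  ncols <- vapply(vals, ncol, integer(1))
  out <- do.call(cbind, vals)
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_op(out, ins, function(g) {
    lapply(seq_along(ins), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# Per-image global average pooling: x [B*H*W, C] -> [B, C].
# `img` is the image id per row (1..B).
ag_gap_rows <- function(x, img, npix) {
  xv <- val(x)
  out <- crossprod(group_indicator(img), xv) / npix
  ag_op(out, list(x), function(g) {
    list(g[img, , drop = FALSE] / npix)
  })
}
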