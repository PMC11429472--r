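# Independent brute-force oracles (scalar loops, no package internals) and
# shared fixtures.

ns <- asNamespace("fundusseg")

# squeeze-excitation gate, elementwise
oracle_se_gate <- function(x, W, b) {
  C <- dim(x)[1]
  out <- array(0, dim(x))
  for (cc in seq_len(C)) {
    gapv <- numeric(C)
    for (c2 in seq_len(C)) gapv[c2] <- mean(x[c2, , ])
    z <- 0
    for (c2 in seq_len(C)) z <- z + gapv[c2] * W[c2, cc]
    s <- 1 / (1 + exp(-(z + b[cc])))
    out[cc, , ] <- s * x[cc, , ]
  }
  out
}

oracle_ce <- function(y, p, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(y)) {
    pc <- min(max(p[i], eps), 1 - eps)
    tot <- tot - (y[i] * log(pc) + (1 - y[i]) * log(1 - pc))
  }
  tot / length(y)
}

oracle_dice_loss <- function(y, p, eps = 1e-6) {
  num <- 0; dy <- 0; dp <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] * p[i]
    dy <- dy + y[i]
    dp <- dp + p[i]
  }
  1 - (2 * num + eps) / (dy + dp + eps)
}

oracle_dilate <- function(x, k = 3L, iters = 1L) {
  r <- k %/% 2L
  for (it in seq_len(iters)) {
    out <- x
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      m <- x[i, j]
      for (dy in -r:r) for (dx in -r:r) {
        yy <- i + dy; xx <- j + dx
        if (yy >= 1 && yy <= nrow(x) && xx >= 1 && xx <= ncol(x)) {
          m <- max(m, x[yy, xx])
        }
      }
      out[i, j] <- m
    }
    x <- out
  }
  x
}

oracle_boundary_dice <- function(y, p, k = 3L, eps = 1e-6) {
  yb <- oracle_dilate(y, k) - y
  pb <- oracle_dilate(p, k) - p
  oracle_dice_loss(yb, pb, eps)
}

oracle_iou <- function(X, Y) {
  inter <- 0; uni <- 0
  for (i in seq_along(X)) {
    if (X[i] == 1 && Y[i] == 1) inter <- inter + 1
    if (X[i] == 1 || Y[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

oracle_dice_coef <- function(X, Y) {
  inter <- 0; s <- 0
  for (i in seq_along(X)) {
    if (X[i] == 1 && Y[i] == 1) inter <- inter + 1
    s <- s + X[i] + Y[i]
  }
  if (s == 0) 1 else 2 * inter / s
}

# per-pixel dynamic head (channel chain 3 -> 8 -> 8 -> 1)
oracle_dynhead <- function(Fp, params) {
  W1 <- matrix(params[1:24], 3, 8);   b1 <- params[25:32]
  W2 <- matrix(params[33:96], 8, 8);  b2 <- params[97:104]
  W3 <- matrix(params[105:112], 8, 1); b3 <- params[113]
  H <- dim(Fp)[2]; W <- dim(Fp)[3]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- Fp[, i, j]
    h1 <- pmax(as.numeric(v %*% W1) + b1, 0)
    h2 <- pmax(as.numeric(h1 %*% W2) + b2, 0)
    z <- sum(h2 * W3) + b3
    out[i, j] <- 1 / (1 + exp(-z))
  }
  out
}

# connected components of a binary matrix (4-neighbourhood)
count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] == 1 && lab[i, j] == 0L) {
      comp <- comp + 1L
      stack <- list(c(i, j))
      lab[i, j] <- comp
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          y <- p[1] + d[1]; x <- p[2] + d[2]
          if (y >= 1 && y <= nrow(m) && x >= 1 && x <= ncol(m) &&
              m[y, x] == 1 && lab[y, x] == 0L) {
            lab[y, x] <- comp
            stack[[length(stack) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  comp
}

# central-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# shared micro model + samples, built once per test run
.fix <- new.env()
micro_cfg <- function() {
  if (is.null(.fix$cfg)) .fix$cfg <- model_config(input_size = 64L, micro_scale = 4L)
  .fix$cfg
}
micro_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_model(micro_cfg(), seed = 11L)
  .fix$model
}
micro_samples <- function(n = 4L, seed = 5L) {
  key <- paste0("s", n, "_", seed)
  if (is.null(.fix[[key]])) {
    sc <- synth_config(image_size = 64L, n_images = n, seed = seed)
    .fix[[key]] <- lapply(seq_len(n) - 1L, function(i) generate_sample(sc, i))
  }
  .fix[[key]]
}
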