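# Spatial network operations on the internal feature layout.
#
# A feature map batch is stored as a matrix [B*H*W, C]: rows are ordered
# image-major, then raster-scan (row y major, column x minor) within an image.
# All 1x1 convolutions are therefore plain matrix products; strided
# patchifications are row/column rearrangements; depthwise and transposed
# convolutions decompose into per-offset gathers/scatters plus BLAS products.

.ixc <- new.env(parent = emptyenv())  # index cache keyed by shape strings

ix_cache <- function(key, make) {
  if (is.null(.ixc[[key]])) .ixc[[key]] <- make()
  .ixc[[key]]
}

# Dense group-indicator matrix [length(img), B] for pooled reductions.
group_indicator <- function(img) {
  B <- max(img)
  ix_cache(paste("ind", length(img), B, paste0(range(img), collapse = ":")),
           function() {
    m <- matrix(0, length(img), B)
    m[cbind(seq_along(img), img)] <- 1
    m
  })
}

# Padded index structure: `i` is a safe source-row vector (out-of-bounds
# entries redirected to row 1), `na` lists the out-of-bounds targets, `ok`
# flags in-bounds ones, `raw` keeps the original NA-bearing vector.
padded_idx <- function(raw) {
  nas <- which(is.na(raw))
  i <- raw
  if (length(nas)) i[nas] <- 1L
  list(i = i, na = nas, ok = !is.na(raw), raw = raw)
}

# Source-row index for reading each target row at spatial offset (dy, dx);
# out-of-image sources are zero padded.
shift_idx <- function(B, H, W, dy, dx) {
  ix_cache(paste("sh", B, H, W, dy, dx), function() {
    ty <- rep(seq_len(H), each = W)
    tx <- rep(seq_len(W), times = H)
    sy <- ty + dy
    sx <- tx + dx
    ok <- sy >= 1L & sy <= H & sx >= 1L & sx <= W
    base <- ifelse(ok, (sy - 1L) * W + sx, NA_integer_)
    padded_idx(rep(base, times = B) +
                 rep((seq_len(B) - 1L) * H * W, each = H * W))
  })
}

# Gather rows of a plain matrix through a padded index (pads become zeros).
gather0 <- function(x, p) {
  out <- x[p$i, , drop = FALSE]
  if (length(p$na)) out[p$na, ] <- 0
  out
}

# ---- depthwise convolution (k x k, stride 1, zero padding k%/%2) ------------

# Combined gather index over all k^2 offsets (forward and reversed), plus the
# fold groups for a single rowsum pass.
dw_cache <- function(B, H, Wd, k) {
  ix_cache(paste("dw", B, H, Wd, k), function() {
    r <- k %/% 2L
    dys <- rep(-r:r, each = k); dxs <- rep(-r:r, times = k)
    S <- B * H * Wd
    fwd <- unlist(lapply(seq_len(k * k), function(o)
      shift_idx(B, H, Wd, dys[o], dxs[o])$raw))
    rev <- unlist(lapply(seq_len(k * k), function(o)
      shift_idx(B, H, Wd, -dys[o], -dxs[o])$raw))
    list(fwd = padded_idx(fwd), rev = padded_idx(rev),
         wrep = rep(seq_len(k * k), each = S),
         grp_s = rep(seq_len(S), times = k * k),
         dys = dys, dxs = dxs, S = S)
  })
}

# W: [k*k, C] (offset-major), b: [C]
ag_dwconv <- function(x, W, b, B, H, Wd, k) {
  stopifnot(k %% 2L == 1L)
  xv <- val(x); Wv <- val(W); bv <- val(b)
  S <- nrow(xv); C <- ncol(xv)
  nofs <- k * k
  fold_s <- function(m) {           # [nofs*S, C] blocked by offset -> [S, C]
    dim(m) <- c(S, nofs, C)
    colSums(aperm(m, c(2L, 1L, 3L)))
  }
  fold_o <- function(m) {           # -> [nofs, C], summing within offsets
    dim(m) <- c(S, nofs, C)
    colSums(m)
  }
  if (nofs * S * C <= 0L) {   # blocked path disabled: slower in practice
    cc <- dw_cache(B, H, Wd, k)
    Wbig <- Wv[cc$wrep, , drop = FALSE]
    out <- fold_s(gather0(xv, cc$fwd) * Wbig) + rep(bv, each = S)
    ag_op(out, list(x, W, b), function(g) {
      gx <- fold_s(gather0(g, cc$rev) * Wbig)
      gW <- fold_o(gather0(xv, cc$fwd) * g[cc$grp_s, , drop = FALSE])
      list(gx, gW, colSums(g))
    })
  } else {
    r <- k %/% 2L
    dys <- rep(-r:r, each = k); dxs <- rep(-r:r, times = k)
    out <- matrix(rep(bv, each = S), S, C)
    for (o in seq_len(nofs)) {
      idx <- shift_idx(B, H, Wd, dys[o], dxs[o])
      if (length(idx$na) == S) next
      out <- out + gather0(xv, idx) * rep(Wv[o, ], each = S)
    }
    ag_op(out, list(x, W, b), function(g) {
      gx <- matrix(0, S, C)
      gW <- matrix(0, nofs, C)
      for (o in seq_len(nofs)) {
        idx  <- shift_idx(B, H, Wd, dys[o], dxs[o])
        if (length(idx$na) == S) next
        oidx <- shift_idx(B, H, Wd, -dys[o], -dxs[o])
        gx <- gx + gather0(g, oidx) * rep(Wv[o, ], each = S)
        gW[o, ] <- colSums(gather0(xv, idx) * g)
      }
      list(gx, gW, colSums(g))
    })
  }
}

# ---- transposed convolution -------------------------------------------------

# Upsamples H x W -> (s*H) x (s*W).  For stride 2 the kernel is 3x3 (zero
# insertion followed by a same-padded 3x3 convolution); for stride 4 the
# kernel is 4x4 so that every output pixel receives exactly one contribution.
# W: [k*k*Cin, Cout] (offset-major row blocks), b: [Cout].
convT_tidx <- function(B, H, Wd, s, dy, dx) {
  ix_cache(paste("ct", B, H, Wd, s, dy, dx), function() {
    ty <- (rep(seq_len(H), each = Wd) - 1L) * s + 1L + dy
    tx <- (rep(seq_len(Wd), times = H) - 1L) * s + 1L + dx
    ok <- ty >= 1L & ty <= s * H & tx >= 1L & tx <= s * Wd
    base <- ifelse(ok, (ty - 1L) * (s * Wd) + tx, NA_integer_)
    padded_idx(rep(base, times = B) +
                 rep((seq_len(B) - 1L) * s * s * H * Wd, each = H * Wd))
  })
}

convT_offsets <- function(k, s) {
  if (k == s) 0:(k - 1L) else (-(k %/% 2L)):(k %/% 2L)
}

ag_convT <- function(x, W, b, B, H, Wd, stride, k = if (stride == 4L) 4L else 3L) {
  xv <- val(x); Wv <- val(W); bv <- val(b)
  S <- nrow(xv); Cin <- ncol(xv); Cout <- length(bv)
  So <- S * stride * stride
  dr <- convT_offsets(k, stride)
  out <- matrix(rep(bv, each = So), So, Cout)
  o <- 0L
  for (dy in dr) for (dx in dr) {
    o <- o + 1L
    Wo <- Wv[(o - 1L) * Cin + seq_len(Cin), , drop = FALSE]
    tt <- convT_tidx(B, H, Wd, stride, dy, dx)
    okr <- tt$ok
    contrib <- xv[okr, , drop = FALSE] %*% Wo
    out[tt$raw[okr], ] <- out[tt$raw[okr], , drop = FALSE] + contrib
  }
  ag_op(out, list(x, W, b), function(g) {
    gx <- matrix(0, S, Cin)
    gW <- matrix(0, k * k * Cin, Cout)
    o <- 0L
    for (dy in dr) for (dx in dr) {
      o <- o + 1L
      Wo <- Wv[(o - 1L) * Cin + seq_len(Cin), , drop = FALSE]
      tt <- convT_tidx(B, H, Wd, stride, dy, dx)
      gsel <- gather0(g, tt)                    # [S, Cout]
      gx <- gx + gsel %*% t(Wo)
      gW[(o - 1L) * Cin + seq_len(Cin), ] <- crossprod(xv, gsel)
    }
    list(gx, gW, colSums(g))
  })
}

# ---- space-to-depth on the row layout --------------------------------------

s2d_src_idx <- function(B, H, Wd, bl, u, v) {
  ix_cache(paste("s2d", B, H, Wd, bl, u, v), function() {
    Ho <- H %/% bl; Wo <- Wd %/% bl
    i <- rep(seq_len(Ho), each = Wo)
    j <- rep(seq_len(Wo), times = Ho)
    y <- (i - 1L) * bl + u + 1L
    x <- (j - 1L) * bl + v + 1L
    base <- (y - 1L) * Wd + x
    rep(base, times = B) + rep((seq_len(B) - 1L) * H * Wd, each = Ho * Wo)
  })
}

# x [B*H*W, C] -> [B*(H/bl)*(W/bl), C*bl^2]; output channel (c, u, v) sits at
# column c*bl^2 + u*bl + v (all zero based), matching the array-level contract.
ag_s2d_rows <- function(x, B, H, Wd, bl) {
  stopifnot(H %% bl == 0L, Wd %% bl == 0L)
  xv <- val(x)
  C <- ncol(xv)
  So <- nrow(xv) %/% (bl * bl)
  out <- matrix(0, So, C * bl * bl)
  for (u in 0:(bl - 1L)) for (v in 0:(bl - 1L)) {
    cols <- (seq_len(C) - 1L) * bl * bl + u * bl + v + 1L
    out[, cols] <- xv[s2d_src_idx(B, H, Wd, bl, u, v), , drop = FALSE]
  }
  ag_op(out, list(x), function(g) {
    gx <- matrix(0, nrow(xv), C)
    for (u in 0:(bl - 1L)) for (v in 0:(bl - 1L)) {
      cols <- (seq_len(C) - 1L) * bl * bl + u * bl + v + 1L
      gx[s2d_src_idx(B, H, Wd, bl, u, v), ] <- g[, cols, drop = FALSE]
    }
    list(gx)
  })
}

# ---- iterated window max filter (soft morphological dilation) ---------------

# x: single-column matrix [B*H*W, 1].  Gradient flows to the argmax source.
ag_maxfilter <- function(x, B, H, Wd, k = 3L, iters = 1L) {
  stopifnot(k %% 2L == 1L, k >= 3L)
  r <- k %/% 2L
  xv <- as.numeric(val(x))
  S <- length(xv)
  best <- xv
  prov <- seq_len(S)
  dys <- rep(-r:r, each = k); dxs <- rep(-r:r, times = k)
  for (it in seq_len(iters)) {
    cur <- best
    curprov <- prov
    for (o in seq_len(k * k)) {
      if (dys[o] == 0L && dxs[o] == 0L) next
      idx <- shift_idx(B, H, Wd, dys[o], dxs[o])
      cand <- cur[idx$i]
      if (length(idx$na)) cand[idx$na] <- -Inf
      cprov <- curprov[idx$i]
      upd <- cand > best
      best[upd] <- cand[upd]
      prov[upd] <- cprov[upd]
    }
  }
  ag_op(matrix(best, S, 1L), list(x), function(g) {
    acc <- rowsum(as.numeric(g), group = prov, reorder = FALSE)
    gx <- numeric(S)
    gx[as.integer(rownames(acc))] <- acc[, 1L]
    list(matrix(gx, S, 1L))
  })
}

# ---- global response normalisation (per image, across channels) -------------

# x [B*H*W, C]; img: image id per row; gamma, beta: [C]
ag_grn <- function(x, gamma, beta, img, eps = 1e-6) {
  xv <- val(x)
  C <- ncol(xv)
  ind <- group_indicator(img)
  s2 <- crossprod(ind, xv * xv)                           # [B, C]
  G <- sqrt(s2 + eps)
  M <- rowMeans(G)
  N <- G / (M + eps)                                      # [B, C]
  Ne <- N[img, , drop = FALSE]
  gv <- val(gamma); bv <- val(beta)
  n <- nrow(xv)
  out <- xv * Ne * rep(gv, each = n) + rep(bv, each = n) + xv
  ag_op(out, list(x, gamma, beta), function(g) {
    gN <- crossprod(ind, g * xv) * rep(gv, each = nrow(G))
    gG <- gN / (M + eps) - (rowSums(gN * G) / (C * (M + eps)^2))
    gs2 <- gG / (2 * G)
    gx <- g * (Ne * rep(gv, each = n) + 1) + 2 * xv * gs2[img, , drop = FALSE]
    list(gx, colSums(g * xv * Ne), colSums(g))
  })
}

# ---- windowed multi-head self attention -------------------------------------

# qkv: [nwin*wlen, 3C] with rows grouped window-major; posbias: [wlen*wlen,
# heads] or NULL; mask: [wlen, wlen, m] additive mask (or NULL) with
# mask_id[w] selecting the slice for window w.
ag_window_attention <- function(qkv, nwin, wlen, heads, posbias = NULL,
                                mask = NULL, mask_id = NULL) {
  qv <- val(qkv)
  C <- ncol(qv) %/% 3L
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  pb <- if (is.null(posbias)) NULL else val(posbias)
  out <- matrix(0, nwin * wlen, C)
  Acache <- vector("list", nwin * heads)
  for (w in seq_len(nwin)) {
    rows <- (w - 1L) * wlen + seq_len(wlen)
    mk <- if (!is.null(mask)) mask[, , mask_id[w]] else NULL
    for (h in seq_len(heads)) {
      cq <- (h - 1L) * dh + seq_len(dh)
      q <- qv[rows, cq, drop = FALSE]
      k <- qv[rows, C + cq, drop = FALSE]
      v <- qv[rows, 2L * C + cq, drop = FALSE]
      sc <- tcrossprod(q, k) * scale
      if (!is.null(pb)) sc <- sc + matrix(pb[, h], wlen, wlen)
      if (!is.null(mk)) sc <- sc + mk
      sc <- sc - apply(sc, 1L, max)
      e <- exp(sc)
      A <- e / rowSums(e)
      Acache[[(w - 1L) * heads + h]] <- A
      out[rows, cq] <- A %*% v
    }
  }
  ins <- if (is.null(posbias)) list(qkv) else list(qkv, posbias)
  ag_op(out, ins, function(g) {
    gqkv <- matrix(0, nrow(qv), 3L * C)
    gpb <- if (is.null(pb)) NULL else matrix(0, wlen * wlen, heads)
    for (w in seq_len(nwin)) {
      rows <- (w - 1L) * wlen + seq_len(wlen)
      for (h in seq_len(heads)) {
        cq <- (h - 1L) * dh + seq_len(dh)
        q <- qv[rows, cq, drop = FALSE]
        k <- qv[rows, C + cq, drop = FALSE]
        v <- qv[rows, 2L * C + cq, drop = FALSE]
        A <- Acache[[(w - 1L) * heads + h]]
        go <- g[rows, cq, drop = FALSE]
        gV <- crossprod(A, go)
        gA <- tcrossprod(go, v)
        gS <- A * (gA - rowSums(gA * A))
        if (!is.null(gpb)) gpb[, h] <- gpb[, h] + as.numeric(gS)
        gqkv[rows, cq] <- gS %*% k * scale
        gqkv[rows, C + cq] <- crossprod(gS, q) * scale
        gqkv[rows, 2L * C + cq] <- gV
      }
    }
    if (is.null(pb)) list(gqkv) else list(gqkv, gpb)
  })
}

# ---- per-image dynamic segmentation head ------------------------------------

# Fp: [B*H*W, 3]; P: [B, 113] flat per-image parameters for the 1x1
# convolution chain 3 -> 8 -> 8 -> 1 (per layer: weights, then bias);
# img: image id per row.  Output: sigmoid probabilities [B*H*W, 1].
DYNHEAD_CHAIN <- c(3L, 8L, 8L, 1L)

dynhead_param_length <- function(chain = DYNHEAD_CHAIN) {
  sum(chain[-length(chain)] * chain[-1L] + chain[-1L])
}

dynhead_split <- function(p, chain = DYNHEAD_CHAIN) {
  out <- list()
  pos <- 0L
  for (l in seq_len(length(chain) - 1L)) {
    ci <- chain[l]; co <- chain[l + 1L]
    W <- matrix(p[pos + seq_len(ci * co)], ci, co)
    pos <- pos + ci * co
    b <- p[pos + seq_len(co)]
    pos <- pos + co
    out[[l]] <- list(W = W, b = b)
  }
  out
}

ag_dynhead <- function(Fp, P, img) {
  Fv <- val(Fp); Pv <- val(P)
  B <- nrow(Pv)
  S <- nrow(Fv)
  out <- matrix(0, S, 1L)
  cache <- vector("list", B)
  rowsofs <- split(seq_len(S), img)
  for (bimg in seq_len(B)) {
    rws <- rowsofs[[bimg]]
    ly <- dynhead_split(Pv[bimg, ])
    X0 <- Fv[rws, , drop = FALSE]
    Z1 <- X0 %*% ly[[1]]$W + rep(ly[[1]]$b, each = length(rws))
    H1 <- Z1 * (Z1 > 0)
    Z2 <- H1 %*% ly[[2]]$W + rep(ly[[2]]$b, each = length(rws))
    H2 <- Z2 * (Z2 > 0)
    Z3 <- H2 %*% ly[[3]]$W + rep(ly[[3]]$b, each = length(rws))
    pr <- 1 / (1 + exp(-Z3))
    out[rws, ] <- pr
    cache[[bimg]] <- list(ly = ly, X0 = X0, Z1 = Z1, H1 = H1, Z2 = Z2,
                          H2 = H2, pr = pr)
  }
  ag_op(out, list(Fp, P), function(g) {
    gF <- matrix(0, S, ncol(Fv))
    gP <- matrix(0, B, ncol(Pv))
    for (bimg in seq_len(B)) {
      rws <- rowsofs[[bimg]]
      cc <- cache[[bimg]]
      ly <- cc$ly
      gZ3 <- g[rws, , drop = FALSE] * cc$pr * (1 - cc$pr)
      gW3 <- crossprod(cc$H2, gZ3); gb3 <- colSums(gZ3)
      gH2 <- gZ3 %*% t(ly[[3]]$W)
      gZ2 <- gH2 * (cc$Z2 > 0)
      gW2 <- crossprod(cc$H1, gZ2); gb2 <- colSums(gZ2)
      gH1 <- gZ2 %*% t(ly[[2]]$W)
      gZ1 <- gH1 * (cc$Z1 > 0)
      gW1 <- crossprod(cc$X0, gZ1); gb1 <- colSums(gZ1)
      gF[rws, ] <- gZ1 %*% t(ly[[1]]$W)
      gP[bimg, ] <- c(as.numeric(gW1), gb1, as.numeric(gW2), gb2,
                      as.numeric(gW3), gb3)
    }
    list(gF, gP)
  })
}

# ---- dense 3x3 convolution (stride 1, zero padding 1) -----------------------

# W: [9*Cin, Cout] (offset-major row blocks), b: [Cout].
ag_conv3x3 <- function(x, W, b, B, H, Wd) {
  xv <- val(x); Wv <- val(W); bv <- val(b)
  S <- nrow(xv); Cin <- ncol(xv); Cout <- length(bv)
  out <- matrix(rep(bv, each = S), S, Cout)
  o <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    o <- o + 1L
    Wo <- Wv[(o - 1L) * Cin + seq_len(Cin), , drop = FALSE]
    out <- out + gather0(xv, shift_idx(B, H, Wd, dy, dx)) %*% Wo
  }
  ag_op(out, list(x, W, b), function(g) {
    gx <- matrix(0, S, Cin)
    gW <- matrix(0, 9L * Cin, Cout)
    o <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      o <- o + 1L
      Wo <- Wv[(o - 1L) * Cin + seq_len(Cin), , drop = FALSE]
      gx <- gx + gather0(g, shift_idx(B, H, Wd, -dy, -dx)) %*% t(Wo)
      gW[(o - 1L) * Cin + seq_len(Cin), ] <-
        crossprod(gather0(xv, shift_idx(B, H, Wd, dy, dx)), g)
    }
    list(gx, gW, colSums(g))
  })
}

# per-channel (column) scaling: out[, c] = x[, c] * gamma[c]
ag_colscale <- function(x, gamma) {
  xv <- val(x); gv <- val(gamma)
  n <- nrow(xv)
  ag_op(xv * rep(gv, each = n), list(x, gamma), function(g) {
    list(g * rep(gv, each = n), colSums(g * xv))
  })
}
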