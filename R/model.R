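# The segmentation model: three-branch multiscale encoder, channel-attention
# feature fusion, transposed-convolution decoder with summed multi-branch
# skip connections, auxiliary classifier, and the prompt-conditioned dynamic
# segmentation head.
#
# Branch 1 consumes the raw image through a 4x patch embedding; branches 2
# and 3 consume the space-to-depth pyramid levels through 1x1-conv stems so
# no further downsampling happens at their first stage.  All branches end at
# H/32 with the same channel width, as the fusion stage requires.

#' Model configuration
#'
#' @param input_size square input edge, divisible by 32 (default 448).
#' @param micro_scale integer divisor applied to the full-scale channel plan
#'   (1 = full size; 4 gives a desk-scale model for fast experiments).
#' @param stage_channels four increasing per-stage channel counts; the
#'   default is the Tiny-variant plan `c(96, 192, 384, 768) / micro_scale`.
#' @param swin_depths,conv_depths per-stage block counts of the attention and
#'   convolutional branches (Tiny defaults `c(2,2,6,2)` and `c(3,3,9,3)`).
#' @param window_size attention window edge (7 at full scale).
#' @param head_dim attention head width; every stage channel count must be a
#'   multiple of it.
#' @param center_branch backbone of the central (raw-image) branch:
#'   `"swin"` (windowed attention, default) or `"convnext"`; the side
#'   branches use the other family.
#' @param encoder_variant `"multiscale"` (default three-branch encoder) or a
#'   single-branch ablation: `"swin_only"`, `"convnext_only"`,
#'   `"resnet50_only"` (residual-bottleneck fallback).
#' @param convnext_version `"v2"` (global response normalisation, default)
#'   or `"v1"` (layer scale).
#' @param cls_hidden hidden width of the auxiliary classifier MLP.
#' @param controller_hidden widths of the two hidden controller layers.
#' @param d_text text-embedding width (512).
#' @param text_encoder `"hash"` or `"clip"` (see [make_text_encoder()]).
#' @param class_names,template prompt classes and template
#'   (see [prompt_template()]).
#' @return list of class `model_config`.
#' @export
model_config <- function(input_size = 448L, micro_scale = 1L,
                         stage_channels = NULL,
                         swin_depths = c(2L, 2L, 6L, 2L),
                         conv_depths = c(3L, 3L, 9L, 3L),
                         window_size = NULL, head_dim = NULL,
                         center_branch = c("swin", "convnext"),
                         encoder_variant = c("multiscale", "swin_only",
                                             "convnext_only", "resnet50_only"),
                         convnext_version = c("v2", "v1"),
                         cls_hidden = NULL,
                         controller_hidden = c(256L, 256L),
                         d_text = 512L,
                         text_encoder = "hash",
                         class_names = c("benign tumor", "malignant tumor"),
                         template = prompt_template(class_names)) {
  center_branch <- match.arg(center_branch)
  encoder_variant <- match.arg(encoder_variant)
  convnext_version <- match.arg(convnext_version)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (is.null(stage_channels)) {
    stage_channels <- c(96L, 192L, 384L, 768L) %/% micro_scale
  }
  if (is.null(head_dim)) head_dim <- max(8L, 32L %/% micro_scale)
  if (is.null(window_size)) window_size <- if (micro_scale > 1L) 4L else 7L
  if (is.null(cls_hidden)) cls_hidden <- max(16L, 256L %/% micro_scale)
  sc <- as.integer(stage_channels)
  stopifnot(length(sc) == 4L, all(diff(sc) > 0))
  if (any(sc %% head_dim != 0L)) {
    stop("every stage channel count must be a multiple of head_dim")
  }
  structure(list(
    input_size = as.integer(input_size), micro_scale = as.integer(micro_scale),
    stage_channels = sc, swin_depths = as.integer(swin_depths),
    conv_depths = as.integer(conv_depths),
    resnet_depths = c(3L, 4L, 6L, 3L),
    window_size = as.integer(window_size), head_dim = as.integer(head_dim),
    center_branch = center_branch, encoder_variant = encoder_variant,
    convnext_version = convnext_version,
    cls_hidden = as.integer(cls_hidden),
    controller_hidden = as.integer(controller_hidden),
    d_text = as.integer(d_text), text_encoder = text_encoder,
    class_names = class_names, template = template,
    decoder_channels = c(sc[3], sc[2], sc[1], 3L)
  ), class = "model_config")
}

# Branch layout derived from the config: which backbone runs where.
branch_layout <- function(cfg) {
  side <- if (cfg$center_branch == "swin") "convnext" else "swin"
  switch(cfg$encoder_variant,
    multiscale = list(
      list(name = "b1", type = cfg$center_branch, in_ch = 3L,
           patchify = 4L, stages = 1:4),
      list(name = "b2", type = side, in_ch = 96L, patchify = 1L, stages = 1:4),
      list(name = "b3", type = side, in_ch = 192L, patchify = 1L, stages = 2:4)),
    swin_only = list(list(name = "b1", type = "swin", in_ch = 3L,
                          patchify = 4L, stages = 1:4)),
    convnext_only = list(list(name = "b1", type = "convnext", in_ch = 3L,
                              patchify = 4L, stages = 1:4)),
    resnet50_only = list(list(name = "b1", type = "resnet", in_ch = 3L,
                              patchify = 4L, stages = 1:4))
  )
}

branch_depths <- function(cfg, type) {
  switch(type, swin = cfg$swin_depths, convnext = cfg$conv_depths,
         resnet = cfg$resnet_depths)
}

# Stage spatial resolution (edge) for the built input size.
stage_res <- function(cfg, st) cfg$input_size %/% (4L * 2L^(st - 1L))

# ---- parameter construction -------------------------------------------------

reg_add <- function(reg, name, value) {
  reg$params[[name]] <- ag_param(value, name)
  invisible(NULL)
}

build_swin_stage_params <- function(reg, pfx, cfg, st) {
  C <- cfg$stage_channels[st]
  heads <- C %/% cfg$head_dim
  ws <- min(cfg$window_size, stage_res(cfg, st))
  wlen <- ws * ws
  for (bk in seq_len(cfg$swin_depths[st])) {
    p <- sprintf("%s.s%d.b%d.", pfx, st, bk)
    reg_add(reg, paste0(p, "ln1g"), rep(1, C))
    reg_add(reg, paste0(p, "ln1b"), rep(0, C))
    reg_add(reg, paste0(p, "qkvW"), init_linear(C, 3L * C, sd = 0.02))
    reg_add(reg, paste0(p, "qkvb"), rep(0, 3L * C))
    reg_add(reg, paste0(p, "projW"), init_linear(C, C, sd = 0.02))
    reg_add(reg, paste0(p, "projb"), rep(0, C))
    reg_add(reg, paste0(p, "pos"), matrix(0, wlen * wlen, heads))
    reg_add(reg, paste0(p, "ln2g"), rep(1, C))
    reg_add(reg, paste0(p, "ln2b"), rep(0, C))
    reg_add(reg, paste0(p, "fc1W"), init_linear(C, 4L * C, sd = 0.02))
    reg_add(reg, paste0(p, "fc1b"), rep(0, 4L * C))
    reg_add(reg, paste0(p, "fc2W"), init_linear(4L * C, C, sd = 0.02))
    reg_add(reg, paste0(p, "fc2b"), rep(0, C))
  }
}

build_convnext_stage_params <- function(reg, pfx, cfg, st) {
  C <- cfg$stage_channels[st]
  for (bk in seq_len(cfg$conv_depths[st])) {
    p <- sprintf("%s.s%d.b%d.", pfx, st, bk)
    reg_add(reg, paste0(p, "dwW"), matrix(trunc_normal(49L * C), 49L, C))
    reg_add(reg, paste0(p, "dwb"), rep(0, C))
    reg_add(reg, paste0(p, "lng"), rep(1, C))
    reg_add(reg, paste0(p, "lnb"), rep(0, C))
    reg_add(reg, paste0(p, "pw1W"), init_linear(C, 4L * C, sd = 0.02))
    reg_add(reg, paste0(p, "pw1b"), rep(0, 4L * C))
    if (cfg$convnext_version == "v2") {
      reg_add(reg, paste0(p, "grng"), rep(0, 4L * C))
      reg_add(reg, paste0(p, "grnb"), rep(0, 4L * C))
    }
    reg_add(reg, paste0(p, "pw2W"), init_linear(4L * C, C, sd = 0.02))
    reg_add(reg, paste0(p, "pw2b"), rep(0, C))
    if (cfg$convnext_version == "v1") {
      reg_add(reg, paste0(p, "lsg"), rep(1e-6, C))
    }
  }
}

build_resnet_stage_params <- function(reg, pfx, cfg, st) {
  C <- cfg$stage_channels[st]
  Cm <- max(4L, C %/% 4L)
  for (bk in seq_len(cfg$resnet_depths[st])) {
    p <- sprintf("%s.s%d.b%d.", pfx, st, bk)
    reg_add(reg, paste0(p, "w1"), init_linear(C, Cm, sd = 0.02))
    reg_add(reg, paste0(p, "b1"), rep(0, Cm))
    reg_add(reg, paste0(p, "w2"), matrix(trunc_normal(9L * Cm * Cm), 9L * Cm, Cm))
    reg_add(reg, paste0(p, "b2"), rep(0, Cm))
    reg_add(reg, paste0(p, "w3"), init_linear(Cm, C, sd = 0.02))
    reg_add(reg, paste0(p, "b3"), rep(0, C))
  }
}

build_branch_params <- function(reg, bd, cfg) {
  sc <- cfg$stage_channels
  st0 <- bd$stages[1]
  in_ch <- if (bd$patchify == 4L) bd$in_ch * 16L else bd$in_ch
  pfx <- bd$name
  reg_add(reg, paste0(pfx, ".stemW"), init_linear(in_ch, sc[st0]))
  reg_add(reg, paste0(pfx, ".stemb"), rep(0, sc[st0]))
  reg_add(reg, paste0(pfx, ".stemlng"), rep(1, sc[st0]))
  reg_add(reg, paste0(pfx, ".stemlnb"), rep(0, sc[st0]))
  for (st in bd$stages) {
    if (st > st0) {
      p <- sprintf("%s.down%d.", pfx, st)
      Cp <- sc[st - 1L]
      if (bd$type == "swin") {
        reg_add(reg, paste0(p, "lng"), rep(1, 4L * Cp))
        reg_add(reg, paste0(p, "lnb"), rep(0, 4L * Cp))
        reg_add(reg, paste0(p, "W"), init_linear(4L * Cp, sc[st]))
      } else {
        reg_add(reg, paste0(p, "lng"), rep(1, Cp))
        reg_add(reg, paste0(p, "lnb"), rep(0, Cp))
        reg_add(reg, paste0(p, "W"), init_linear(4L * Cp, sc[st]))
        reg_add(reg, paste0(p, "b"), rep(0, sc[st]))
      }
    }
    switch(bd$type,
      swin = build_swin_stage_params(reg, pfx, cfg, st),
      convnext = build_convnext_stage_params(reg, pfx, cfg, st),
      resnet = build_resnet_stage_params(reg, pfx, cfg, st))
  }
  # final norm on the branch output (the fusion stage expects unit scale)
  reg_add(reg, paste0(pfx, ".outlng"), rep(1, sc[4]))
  reg_add(reg, paste0(pfx, ".outlnb"), rep(0, sc[4]))
}

#' Build a segmentation model with freshly initialised weights
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `fundusseg_model`: `cfg`, named parameter list
#'   `params`, and the frozen `text_encoder`.
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  reg <- new.env(parent = emptyenv())
  reg$params <- list()
  with_private_seed(as.integer(seed) + 1234L, {
    branches <- branch_layout(cfg)
    for (bd in branches) build_branch_params(reg, bd, cfg)
    C4 <- cfg$stage_channels[4]
    if (length(branches) > 1L) {
      reg_add(reg, "fuse.g2W", init_linear(C4, C4, sd = 0.02))
      reg_add(reg, "fuse.g2b", rep(0, C4))
      reg_add(reg, "fuse.g3W", init_linear(C4, C4, sd = 0.02))
      reg_add(reg, "fuse.g3b", rep(0, C4))
    }
    # auxiliary classifier
    reg_add(reg, "cls.W1", init_linear(C4, cfg$cls_hidden))
    reg_add(reg, "cls.b1", rep(0, cfg$cls_hidden))
    reg_add(reg, "cls.W2", init_linear(cfg$cls_hidden, 2L))
    reg_add(reg, "cls.b2", rep(0, 2L))
    # controller: (C4 + d_text) -> hidden -> hidden -> P
    P <- dynhead_param_length()
    ch <- cfg$controller_hidden
    reg_add(reg, "cont.W1", init_linear(C4 + cfg$d_text, ch[1]))
    reg_add(reg, "cont.b1", rep(0, ch[1]))
    reg_add(reg, "cont.W2", init_linear(ch[1], ch[2]))
    reg_add(reg, "cont.b2", rep(0, ch[2]))
    reg_add(reg, "cont.W3", init_linear(ch[2], P, sd = 0.01))
    # The controller bias acts as the default head: a He-scaled random MLP
    # the per-image modulation is added to.  Without it the generated weights
    # start near zero and no gradient reaches the decoder.
    chain <- DYNHEAD_CHAIN
    b3 <- unlist(lapply(seq_len(length(chain) - 1L), function(l) {
      ci <- chain[l]; co <- chain[l + 1L]
      c(trunc_normal(ci * co, sd = sqrt(2 / ci)), rep(0, co))
    }))
    reg_add(reg, "cont.b3", b3)
    # decoder blocks and skip projections
    dc <- cfg$decoder_channels
    cin <- c(C4, dc[1], dc[2], dc[3])
    ups <- c(2L, 2L, 2L, 4L)
    for (i in 1:4) {
      p <- sprintf("dec%d.", i)
      k <- if (ups[i] == 4L) 4L else 3L
      reg_add(reg, paste0(p, "c1W"), init_linear(cin[i], dc[i]))
      reg_add(reg, paste0(p, "c1b"), rep(0, dc[i]))
      reg_add(reg, paste0(p, "ctW"),
              matrix(trunc_normal(k * k * dc[i] * dc[i],
                                  sd = sqrt(2 / (k * k * dc[i]))),
                     k * k * dc[i], dc[i]))
      reg_add(reg, paste0(p, "ctb"), rep(0, dc[i]))
      reg_add(reg, paste0(p, "c2W"), init_linear(dc[i], dc[i]))
      reg_add(reg, paste0(p, "c2b"), rep(0, dc[i]))
    }
    # skip projections at H/16, H/8, H/4 (stage maps from every branch that
    # reaches the resolution, concatenated then 1x1-projected)
    for (i in 1:3) {
      st <- 4L - i                       # stage whose maps sit at this res
      nb <- sum(vapply(branches, function(b) st %in% b$stages, logical(1)))
      reg_add(reg, sprintf("skip%d.W", i),
              init_linear(nb * cfg$stage_channels[st], dc[i]))
      reg_add(reg, sprintf("skip%d.b", i), rep(0, dc[i]))
    }
  })
  structure(list(cfg = cfg, params = reg$params,
                 text_encoder = make_text_encoder(cfg$text_encoder, cfg$d_text),
                 version = 1L),
            class = "fundusseg_model")
}

model_param_count <- function(model, prefix = NULL) {
  nm <- names(model$params)
  if (!is.null(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(model$params[nm], function(p) length(p$v), numeric(1)))
}

# ---- attention window layout ------------------------------------------------

swin_layout <- function(B, h, w, ws, shift) {
  key <- paste("swl", B, h, w, ws, shift)
  ix_cache(key, function() {
    hp <- as.integer(ceiling(h / ws) * ws)
    wp <- as.integer(ceiling(w / ws) * ws)
    nwh <- hp %/% ws; nww <- wp %/% ws
    nwin <- nwh * nww
    wlen <- ws * ws
    # padded (shifted) coordinates in window-partition order
    wi_y <- rep(seq_len(nwh), each = nww * wlen)
    wi_x <- rep(rep(seq_len(nww), each = wlen), times = nwh)
    u <- rep(rep(seq_len(ws), each = ws), times = nwin)
    v <- rep(seq_len(ws), times = nwin * ws)
    yp <- (wi_y - 1L) * ws + u
    xp <- (wi_x - 1L) * ws + v
    yo <- ((yp - 1L + shift) %% hp) + 1L
    xo <- ((xp - 1L + shift) %% wp) + 1L
    valid <- yo <= h & xo <= w
    src <- ifelse(valid, (yo - 1L) * w + xo, NA_integer_)
    # inverse: original row -> slot position
    unpart <- integer(h * w)
    unpart[src[valid]] <- which(valid)
    # attention mask: needed when shifting or padding
    need_mask <- shift > 0L || any(!valid)
    mask <- NULL
    if (need_mask) {
      band <- function(o, n) ifelse(o <= n - ws, 0L,
                                    ifelse(o <= n - shift, 1L, 2L))
      id <- ifelse(valid, band(yo, h) * 3L + band(xo, w), -1L)
      mask <- array(0, c(wlen, wlen, nwin))
      for (wi in seq_len(nwin)) {
        ids <- id[(wi - 1L) * wlen + seq_len(wlen)]
        mm <- outer(ids, ids, FUN = function(a, b) ifelse(a == b, 0, -1e9))
        # padded slots must not receive all -inf rows: let them attend to
        # themselves (their outputs are discarded on un-partition)
        diag(mm) <- 0
        mask[, , wi] <- mm
      }
    }
    part_full <- rep(src, times = B) +
      rep((seq_len(B) - 1L) * h * w, each = nwin * wlen)
    unpart_full <- rep(unpart, times = B) +
      rep((seq_len(B) - 1L) * nwin * wlen, each = h * w)
    list(part = part_full, unpart = unpart_full,
         nwin_total = B * nwin, wlen = wlen,
         mask = mask, mask_id = if (need_mask) rep(seq_len(nwin), B) else NULL)
  })
}

# ---- blocks -----------------------------------------------------------------

gp <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("missing parameter: ", name)
  p
}

swin_block_fwd <- function(model, x, p, B, h, w, ws, shift, heads) {
  lay <- swin_layout(B, h, w, ws, shift)
  xn <- ag_layernorm(x, gp(model, paste0(p, "ln1g")), gp(model, paste0(p, "ln1b")))
  qkv <- ag_linear(xn, gp(model, paste0(p, "qkvW")), gp(model, paste0(p, "qkvb")))
  qkvw <- ag_rows(qkv, lay$part)
  att <- ag_window_attention(qkvw, lay$nwin_total, lay$wlen, heads,
                             posbias = gp(model, paste0(p, "pos")),
                             mask = lay$mask, mask_id = lay$mask_id)
  att <- ag_rows(att, lay$unpart)
  x <- ag_add(x, ag_linear(att, gp(model, paste0(p, "projW")),
                           gp(model, paste0(p, "projb"))))
  xn <- ag_layernorm(x, gp(model, paste0(p, "ln2g")), gp(model, paste0(p, "ln2b")))
  hdd <- ag_gelu(ag_linear(xn, gp(model, paste0(p, "fc1W")),
                           gp(model, paste0(p, "fc1b"))))
  ag_add(x, ag_linear(hdd, gp(model, paste0(p, "fc2W")),
                      gp(model, paste0(p, "fc2b"))))
}

convnext_block_fwd <- function(model, x, p, B, h, w) {
  img <- rep(seq_len(B), each = h * w)
  y <- ag_dwconv(x, gp(model, paste0(p, "dwW")), gp(model, paste0(p, "dwb")),
                 B, h, w, 7L)
  y <- ag_layernorm(y, gp(model, paste0(p, "lng")), gp(model, paste0(p, "lnb")))
  y <- ag_linear(y, gp(model, paste0(p, "pw1W")), gp(model, paste0(p, "pw1b")))
  y <- ag_gelu(y)
  if (model$cfg$convnext_version == "v2") {
    y <- ag_grn(y, gp(model, paste0(p, "grng")), gp(model, paste0(p, "grnb")), img)
  }
  y <- ag_linear(y, gp(model, paste0(p, "pw2W")), gp(model, paste0(p, "pw2b")))
  if (model$cfg$convnext_version == "v1") {
    y <- ag_colscale(y, gp(model, paste0(p, "lsg")))
  }
  ag_add(x, y)
}

resnet_block_fwd <- function(model, x, p, B, h, w) {
  y <- ag_relu(ag_linear(x, gp(model, paste0(p, "w1")), gp(model, paste0(p, "b1"))))
  y <- ag_relu(ag_conv3x3(y, gp(model, paste0(p, "w2")), gp(model, paste0(p, "b2")),
                          B, h, w))
  y <- ag_linear(y, gp(model, paste0(p, "w3")), gp(model, paste0(p, "b3")))
  ag_relu(ag_add(x, y))
}

branch_forward <- function(model, bd, x, B, h, w) {
  cfg <- model$cfg
  sc <- cfg$stage_channels
  pfx <- bd$name
  st0 <- bd$stages[1]
  if (bd$patchify == 4L) {
    x <- ag_s2d_rows(x, B, h, w, 4L)
    h <- h %/% 4L; w <- w %/% 4L
  }
  x <- ag_linear(x, gp(model, paste0(pfx, ".stemW")),
                 gp(model, paste0(pfx, ".stemb")))
  x <- ag_layernorm(x, gp(model, paste0(pfx, ".stemlng")),
                    gp(model, paste0(pfx, ".stemlnb")))
  depths <- branch_depths(cfg, bd$type)
  maps <- list()
  for (st in bd$stages) {
    if (st > st0) {
      p <- sprintf("%s.down%d.", pfx, st)
      if (bd$type == "swin") {
        x <- ag_s2d_rows(x, B, h, w, 2L)
        h <- h %/% 2L; w <- w %/% 2L
        x <- ag_layernorm(x, gp(model, paste0(p, "lng")),
                          gp(model, paste0(p, "lnb")))
        x <- ag_linear(x, gp(model, paste0(p, "W")))
      } else {
        x <- ag_layernorm(x, gp(model, paste0(p, "lng")),
                          gp(model, paste0(p, "lnb")))
        x <- ag_s2d_rows(x, B, h, w, 2L)
        h <- h %/% 2L; w <- w %/% 2L
        x <- ag_linear(x, gp(model, paste0(p, "W")), gp(model, paste0(p, "b")))
      }
    }
    if (bd$type == "swin") {
      ws <- min(cfg$window_size, h, w)
      heads <- sc[st] %/% cfg$head_dim
      for (bk in seq_len(depths[st])) {
        shift <- if (bk %% 2L == 0L && ws < min(h, w)) ws %/% 2L else 0L
        x <- swin_block_fwd(model, x, sprintf("%s.s%d.b%d.", pfx, st, bk),
                            B, h, w, ws, shift, heads)
      }
    } else if (bd$type == "convnext") {
      for (bk in seq_len(depths[st])) {
        x <- convnext_block_fwd(model, x, sprintf("%s.s%d.b%d.", pfx, st, bk),
                                B, h, w)
      }
    } else {
      for (bk in seq_len(depths[st])) {
        x <- resnet_block_fwd(model, x, sprintf("%s.s%d.b%d.", pfx, st, bk),
                              B, h, w)
      }
    }
    maps[[as.character(st)]] <- list(x = x, h = h, w = w)
  }
  maps[["4"]]$x <- ag_layernorm(maps[["4"]]$x,
                                gp(model, paste0(pfx, ".outlng")),
                                gp(model, paste0(pfx, ".outlnb")))
  maps
}

# ---- full forward pass ------------------------------------------------------

images_to_rows <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  B <- length(images)
  d <- dim(images[[1]])
  stopifnot(d[1] == 3L)
  rows <- do.call(rbind, lapply(images, chw_to_rows))
  list(x = rows, B = B, H = d[2], W = d[3])
}

#' Forward pass of the segmentation model
#'
#' Builds the three-scale pyramid, encodes it with the branch encoders, fuses
#' the branch outputs with channel-attention gates, classifies the image,
#' fills and embeds the class prompt, generates the dynamic-head parameters,
#' decodes to full resolution and applies the dynamic head.
#'
#' @param model a [build_model()] object.
#' @param images one `[3, H, W]` array or a list of them (equal sizes,
#'   divisible by 32).
#' @param class_labels optional integer vector of ground-truth classes
#'   (0 = benign, 1 = malignant); used for the prompt when `train = TRUE`
#'   (teacher forcing).
#' @param train logical; gradients are recorded only when `TRUE`.
#' @param force_class optional class override for the prompt (prompt-ablation
#'   probe).
#' @return list: `prob` (`[B*H*W, 1]` lesion probabilities, tape node when
#'   training), `prob_maps` (list of `[H, W]` matrices), `class_probs`
#'   (`[B, 2]`), `pred_class` (0/1), `logits`, `F`, `Fp`, branch maps,
#'   `shp = c(B, H, W)`.
#' @export
model_forward <- function(model, images, class_labels = NULL, train = FALSE,
                          force_class = NULL) {
  run <- function() model_forward_impl(model, images, class_labels, train,
                                       force_class)
  if (train) run() else ag_no_grad(run())
}

model_forward_impl <- function(model, images, class_labels, train, force_class) {
  cfg <- model$cfg
  im <- images_to_rows(images)
  B <- im$B; H <- im$H; W <- im$W
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop(sprintf("input %d x %d not divisible by 32", H, W))
  }
  branches <- branch_layout(cfg)
  # input pyramid (constants on the tape)
  I1 <- im$x
  inputs <- list(b1 = I1)
  if (length(branches) > 1L) {
    I2raw <- ag_s2d_rows(I1, B, H, W, 4L)
    inputs$b2 <- cbind(I2raw, I2raw)          # tiled replication 48 -> 96
    inputs$b3 <- ag_s2d_rows(I1, B, H, W, 8L)
  }
  res_in <- c(b1 = H, b2 = H %/% 4L, b3 = H %/% 8L)
  wres_in <- c(b1 = W, b2 = W %/% 4L, b3 = W %/% 8L)
  all_maps <- list()
  for (bd in branches) {
    all_maps[[bd$name]] <- branch_forward(model, bd, inputs[[bd$name]],
                                          B, res_in[[bd$name]],
                                          wres_in[[bd$name]])
  }
  h32 <- H %/% 32L; w32 <- W %/% 32L
  img32 <- rep(seq_len(B), each = h32 * w32)
  F1 <- all_maps$b1[["4"]]$x
  if (length(branches) > 1L) {
    F2 <- all_maps$b2[["4"]]$x
    F3 <- all_maps$b3[["4"]]$x
    stopifnot(identical(dim(val(F1)), dim(val(F2))),
              identical(dim(val(F1)), dim(val(F3))))
    g2 <- ag_sigmoid(ag_linear(ag_gap_rows(F2, img32, h32 * w32),
                               gp(model, "fuse.g2W"), gp(model, "fuse.g2b")))
    g3 <- ag_sigmoid(ag_linear(ag_gap_rows(F3, img32, h32 * w32),
                               gp(model, "fuse.g3W"), gp(model, "fuse.g3b")))
    Ff <- ag_add(F1, ag_add(ag_mul(F2, ag_rows(g2, img32)),
                            ag_mul(F3, ag_rows(g3, img32))))
  } else {
    F2 <- NULL; F3 <- NULL
    Ff <- F1
  }
  # auxiliary classifier on pooled fused features
  gapF <- ag_gap_rows(Ff, img32, h32 * w32)
  logits <- ag_linear(ag_relu(ag_linear(gapF, gp(model, "cls.W1"),
                                        gp(model, "cls.b1"))),
                      gp(model, "cls.W2"), gp(model, "cls.b2"))
  lv <- val(logits)
  e <- exp(lv - apply(lv, 1L, max))
  class_probs <- e / rowSums(e)
  pred_class <- max.col(class_probs) - 1L
  prompt_class <- if (!is.null(force_class)) {
    rep_len(as.integer(force_class), B)
  } else if (train && !is.null(class_labels)) {
    as.integer(class_labels)
  } else {
    pred_class
  }
  emb <- t(vapply(prompt_class, function(ci) {
    model$text_encoder$encode(fill_prompt(cfg$template, ci))
  }, numeric(cfg$d_text)))
  proF <- ag_cbind(gapF, emb)
  hc <- ag_relu(ag_linear(proF, gp(model, "cont.W1"), gp(model, "cont.b1")))
  hc <- ag_relu(ag_linear(hc, gp(model, "cont.W2"), gp(model, "cont.b2")))
  Pdyn <- ag_linear(hc, gp(model, "cont.W3"), gp(model, "cont.b3"))
  # decoder with summed skip connections
  x <- Ff; h <- h32; w <- w32
  ups <- c(2L, 2L, 2L, 4L)
  for (i in 1:4) {
    p <- sprintf("dec%d.", i)
    x <- ag_gelu(ag_linear(x, gp(model, paste0(p, "c1W")),
                           gp(model, paste0(p, "c1b"))))
    x <- ag_gelu(ag_convT(x, gp(model, paste0(p, "ctW")),
                          gp(model, paste0(p, "ctb")), B, h, w, ups[i]))
    h <- h * ups[i]; w <- w * ups[i]
    x <- ag_linear(x, gp(model, paste0(p, "c2W")), gp(model, paste0(p, "c2b")))
    if (i <= 3L) {
      st <- 4L - i
      skips <- list()
      for (bd in branches) {
        m <- all_maps[[bd$name]][[as.character(st)]]
        if (!is.null(m)) skips[[length(skips) + 1L]] <- m$x
      }
      cc <- do.call(ag_cbind, skips)
      x <- ag_add(x, ag_linear(cc, gp(model, sprintf("skip%d.W", i)),
                               gp(model, sprintf("skip%d.b", i))))
    }
  }
  Fp <- x                                       # [B*H*W, 3]
  imgfull <- rep(seq_len(B), each = H * W)
  prob <- ag_dynhead(Fp, Pdyn, imgfull)
  pv <- val(prob)
  prob_maps <- lapply(seq_len(B), function(b) {
    matrix(pv[imgfull == b, 1L], H, W, byrow = TRUE)
  })
  list(prob = prob, prob_maps = prob_maps, class_probs = class_probs,
       pred_class = pred_class, prompt_class = prompt_class, logits = logits,
       F = Ff, F1 = F1, F2 = F2, F3 = F3, Fp = Fp, maps = all_maps,
       dyn_params = val(Pdyn), shp = c(B, H, W), img = imgfull)
}

# ---- spec-level array wrappers ----------------------------------------------

#' Encode one image into the three branch feature maps
#'
#' @param model a [build_model()] object.
#' @param image `[3, H, W]` array.
#' @return list with `F1`, `F2`, `F3` as `[C, H/32, W/32]` arrays (`F2`/`F3`
#'   `NULL` for single-branch variants) and the per-branch `stage_maps`.
#' @export
encode_pyramid <- function(model, image) {
  out <- model_forward(model, image, train = FALSE)
  tomap <- function(nd, h, w) if (is.null(nd)) NULL else rows_to_chw(val(nd), h, w)
  h32 <- out$shp[2] %/% 32L; w32 <- out$shp[3] %/% 32L
  stage_maps <- lapply(out$maps, function(mm) {
    lapply(mm, function(m) rows_to_chw(val(m$x), m$h, m$w))
  })
  list(F1 = tomap(out$F1, h32, w32), F2 = tomap(out$F2, h32, w32),
       F3 = tomap(out$F3, h32, w32), stage_maps = stage_maps)
}

#' Global average pooling of a CHW array
#'
#' @param x `[C, h, w]` array.
#' @return numeric vector of length `C` (the `C x 1 x 1` channel descriptor).
#' @export
gap_chw <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, 1L, mean)
}

#' Squeeze-and-excitation channel gate
#'
#' `out[c, , ] = sigmoid(W gap(x) + b)[c] * x[c, , ]`.
#'
#' @param x `[C, h, w]` array.
#' @param W `[C, C]` gate weight (applied as `t(W) %*% gap`
#'   following the column-weight convention used throughout).
#' @param b length-`C` bias.
#' @return gated array, same shape as `x`; gate values lie strictly in (0,1).
#' @export
se_gate <- function(x, W, b) {
  g <- as.numeric(gap_chw(x) %*% W) + b
  s <- 1 / (1 + exp(-g))
  x * array(s, dim(x))   # recycles along the channel (first) dimension
}

#' Fuse three equally shaped feature maps
#'
#' `F = F1 + gate2(F2) + gate3(F3)` with squeeze-and-excitation gates.
#'
#' @param F1,F2,F3 `[C, h, w]` arrays of identical shape.
#' @param gate2,gate3 lists with elements `W` (`[C, C]`) and `b` (length `C`).
#' @return fused `[C, h, w]` array.
#' @export
fuse_features <- function(F1, F2, F3, gate2, gate3) {
  stopifnot(identical(dim(F1), dim(F2)), identical(dim(F1), dim(F3)))
  F1 + se_gate(F2, gate2$W, gate2$b) + se_gate(F3, gate3$W, gate3$b)
}

#' Classify fused features with the auxiliary MLP
#'
#' @param model a model object.
#' @param F_map `[C_last, h, w]` fused feature array.
#' @return probability vector over (benign, malignant), summing to 1.
#' @export
classify_features <- function(model, F_map) {
  g <- gap_chw(F_map)
  h <- pmax(as.numeric(g %*% val(gp(model, "cls.W1"))) +
              val(gp(model, "cls.b1")), 0)
  z <- as.numeric(h %*% val(gp(model, "cls.W2"))) + val(gp(model, "cls.b2"))
  e <- exp(z - max(z))
  as.numeric(e / sum(e))
}

#' Run the controller on a proF vector
#'
#' @param model a model object.
#' @param proF numeric vector of length `C_last + d_text` (pooled fused
#'   features concatenated with the prompt embedding).
#' @return flat dynamic-head parameter vector of length 113.
#' @export
controller_forward <- function(model, proF) {
  x <- matrix(proF, 1L)
  h <- pmax(x %*% val(gp(model, "cont.W1")) +
              rep(val(gp(model, "cont.b1")), each = 1L), 0)
  h <- pmax(h %*% val(gp(model, "cont.W2")) +
              rep(val(gp(model, "cont.b2")), each = 1L), 0)
  as.numeric(h %*% val(gp(model, "cont.W3")) +
               rep(val(gp(model, "cont.b3")), each = 1L))
}

#' Apply the dynamic segmentation head to a decoded feature map
#'
#' Three 1x1 convolutions with per-image generated parameters
#' (channel chain 3 -> 8 -> 8 -> 1, ReLU between layers, sigmoid output).
#'
#' @param Fp `[3, H, W]` decoded feature array.
#' @param params flat parameter vector of length 113 (layer order, weights
#'   before bias).
#' @return `[H, W]` matrix of probabilities in (0, 1).
#' @export
apply_dynamic_head <- function(Fp, params) {
  stopifnot(length(dim(Fp)) == 3L, dim(Fp)[1] == DYNHEAD_CHAIN[1],
            length(params) == dynhead_param_length())
  ly <- dynhead_split(params)
  X <- chw_to_rows(Fp)
  n <- nrow(X)
  H1 <- pmax(X %*% ly[[1]]$W + rep(ly[[1]]$b, each = n), 0)
  H2 <- pmax(H1 %*% ly[[2]]$W + rep(ly[[2]]$b, each = n), 0)
  Z <- H2 %*% ly[[3]]$W + rep(ly[[3]]$b, each = n)
  matrix(1 / (1 + exp(-Z)), dim(Fp)[2], dim(Fp)[3], byrow = TRUE)
}
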