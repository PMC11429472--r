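# Training pipeline: augmentation, the plateau learning-rate schedule with
# its stopping rule, the optimisation loop, prediction and evaluation.

#' Training configuration
#'
#' @param input_size square training resolution, divisible by 32.
#' @param batch_size images per optimisation step (default 12).
#' @param lr_init initial learning rate (default 2e-4).
#' @param lr_factor multiplicative decay on plateau (0.5).
#' @param plateau_patience epochs without improvement of the best epoch loss
#'   before the rate is cut (20).
#' @param lr_min floor; reaching it stops training (5e-7).
#' @param no_reduction_stop stop after this many consecutive epochs without a
#'   rate reduction (50).
#' @param max_epochs hard epoch cap.
#' @param weight_decay AdamW decoupled weight decay.
#' @param augment logical: apply data augmentation.
#' @param target_mdice optional early-stop target: every `check_every` epochs
#'   the mean training Dice is measured (un-augmented samples, threshold 0.5)
#'   and training stops once it is reached.
#' @param check_every epochs between early-stop checks.
#' @param seed master seed for shuffling, augmentation and initialisation.
#' @param loss a [loss_config()].
#' @param model a [model_config()].
#' @return list of class `train_config`.
#' @export
train_config <- function(input_size = 448L, batch_size = 12L, lr_init = 2e-4,
                         lr_factor = 0.5, plateau_patience = 20L,
                         lr_min = 5e-7, no_reduction_stop = 50L,
                         max_epochs = 200L, weight_decay = 0.01,
                         augment = TRUE, target_mdice = NULL,
                         check_every = 10L, seed = 0L,
                         loss = loss_config(),
                         model = model_config(input_size = input_size)) {
  stopifnot(lr_min < lr_init, plateau_patience >= 1L,
            input_size %% 32L == 0L, batch_size >= 1L)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_factor = lr_factor,
                 plateau_patience = as.integer(plateau_patience),
                 lr_min = lr_min,
                 no_reduction_stop = as.integer(no_reduction_stop),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay,
                 augment = augment, target_mdice = target_mdice,
                 check_every = as.integer(check_every),
                 seed = as.integer(seed),
                 loss = loss, model = model),
            class = "train_config")
}

# ---- learning-rate schedule -------------------------------------------------

#' Initial state for the plateau learning-rate schedule
#'
#' @param cfg a [train_config()] (only the schedule fields are read).
#' @return list of class `train_state`.
#' @export
init_train_state <- function(cfg = train_config()) {
  structure(list(epoch = 0L, lr = cfg$lr_init, best_loss = Inf,
                 epochs_since_improvement = 0L,
                 epochs_since_lr_reduction = 0L, stop = FALSE,
                 lr_factor = cfg$lr_factor, lr_min = cfg$lr_min,
                 plateau_patience = cfg$plateau_patience,
                 no_reduction_stop = cfg$no_reduction_stop),
            class = "train_state")
}

#' Advance the learning-rate schedule by one epoch
#'
#' The rate is halved once the best epoch loss has failed to improve
#' (strictly) for `plateau_patience` consecutive epochs; the plateau and
#' no-reduction counters then reset.  The stop flag is set when the rate
#' reaches `lr_min` or when `no_reduction_stop` consecutive epochs pass
#' without a reduction.  The rate never increases and never drops below
#' `lr_min`.
#'
#' @param state a `train_state`.
#' @param epoch_loss finite training loss of the finished epoch.
#' @return updated `train_state`.
#' @export
lr_schedule_step <- function(state, epoch_loss) {
  if (!is.finite(epoch_loss)) stop("non-finite epoch loss")
  state$epoch <- state$epoch + 1L
  if (epoch_loss < state$best_loss) {
    state$best_loss <- epoch_loss
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  }
  state$epochs_since_lr_reduction <- state$epochs_since_lr_reduction + 1L
  if (state$epochs_since_improvement >= state$plateau_patience) {
    state$lr <- max(state$lr * state$lr_factor, state$lr_min)
    state$epochs_since_improvement <- 0L
    state$epochs_since_lr_reduction <- 0L
    if (state$lr <= state$lr_min) state$stop <- TRUE
  }
  if (state$epochs_since_lr_reduction >= state$no_reduction_stop) {
    state$stop <- TRUE
  }
  state
}

# ---- augmentation -----------------------------------------------------------

rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  grDevices::rgb2hsv(matrix(img, 3L, d[2] * d[3]) * 255, maxColorValue = 255)
}

hsv_to_rgb_arr <- function(hsvm, d) {
  hex <- grDevices::hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ])
  array(grDevices::col2rgb(hex) / 255, d)
}

# Inverse-mapped affine warp.  Mask uses nearest neighbour, image bilinear.
affine_warp <- function(img, mask, out_size, rot = 0, zoom = c(1, 1),
                        shift = c(0, 0)) {
  H <- dim(img)[2]; W <- dim(img)[3]
  oy <- rep(seq_len(out_size), each = out_size)
  ox <- rep(seq_len(out_size), times = out_size)
  cy <- (out_size + 1) / 2; cx <- (out_size + 1) / 2
  u <- (oy - cy) / out_size; v <- (ox - cx) / out_size
  cr <- cos(rot); sr <- sin(rot)
  su <- (cr * u - sr * v) / zoom[1] + shift[1]
  sv <- (sr * u + cr * v) / zoom[2] + shift[2]
  sy <- su * H + (H + 1) / 2
  sx <- sv * W + (W + 1) / 2
  # nearest neighbour for the mask
  ny <- round(sy); nx <- round(sx)
  okn <- ny >= 1 & ny <= H & nx >= 1 & nx <= W
  mo <- numeric(out_size^2)
  mo[okn] <- mask[cbind(ny[okn], nx[okn])]
  mask_out <- matrix(mo, out_size, out_size, byrow = TRUE)
  # bilinear for the image
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  img_out <- array(0, c(3L, out_size, out_size))
  cl <- function(a, n) pmin(pmax(a, 1), n)
  for (ch in 1:3) {
    pl <- img[ch, , ]
    okb <- sy >= 0.5 & sy <= H + 0.5 & sx >= 0.5 & sx <= W + 0.5
    v00 <- pl[cbind(cl(y0, H), cl(x0, W))]
    v01 <- pl[cbind(cl(y0, H), cl(x0 + 1, W))]
    v10 <- pl[cbind(cl(y0 + 1, H), cl(x0, W))]
    v11 <- pl[cbind(cl(y0 + 1, H), cl(x0 + 1, W))]
    px <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
    px[!okb] <- 0
    img_out[ch, , ] <- matrix(px, out_size, out_size, byrow = TRUE)
  }
  list(image = img_out, mask = mask_out)
}

#' Augment a sample
#'
#' Photometric jitter (hue, saturation, brightness) applies to the image
#' only; geometric transforms (translation, zoom, rotation, aspect change,
#' flips, 90-degree rotations) apply identically to image and mask, the mask
#' through nearest-neighbour resampling so it stays binary.  Output is
#' resized to `input_size`.  Uses the current RNG stream.
#'
#' @param sample a `sample_record`.
#' @param input_size output edge.
#' @param enabled if `FALSE`, only the resize happens.
#' @return augmented `sample_record`.
#' @export
augment_sample <- function(sample, input_size, enabled = TRUE) {
  img <- sample$image; msk <- sample$mask
  if (enabled) {
    hsvm <- rgb_to_hsv_arr(img)
    hsvm[1, ] <- (hsvm[1, ] + stats::runif(1, -0.03, 0.03)) %% 1
    hsvm[2, ] <- pmin(pmax(hsvm[2, ] * stats::runif(1, 0.85, 1.15), 0), 1)
    hsvm[3, ] <- pmin(pmax(hsvm[3, ] * stats::runif(1, 0.85, 1.15), 0), 1)
    img <- hsv_to_rgb_arr(hsvm, dim(img))
    zoom <- stats::runif(1, 0.9, 1.1)
    aspect <- stats::runif(1, 0.95, 1.05)
    wr <- affine_warp(img, msk, input_size,
                      rot = stats::runif(1, -pi / 12, pi / 12),
                      zoom = c(zoom * aspect, zoom / aspect),
                      shift = stats::runif(2, -0.05, 0.05))
    img <- wr$image; msk <- wr$mask
    if (stats::runif(1) < 0.5) {              # horizontal flip
      img <- img[, , rev(seq_len(dim(img)[3])), drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {              # vertical flip
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
    k90 <- sample.int(4L, 1L) - 1L            # 90-degree rotations
    for (r in seq_len(k90)) {
      img <- aperm(img, c(1, 3, 2))[, rev(seq_len(dim(img)[3])), , drop = FALSE]
      msk <- t(msk)[rev(seq_len(ncol(msk))), , drop = FALSE]
    }
  } else if (dim(img)[2] != input_size || dim(img)[3] != input_size) {
    wr <- affine_warp(img, msk, input_size)
    img <- wr$image; msk <- wr$mask
  }
  structure(list(image = img, mask = msk, label = sample$label,
                 lesion_area = sum(msk), id = sample$id),
            class = "sample_record")
}

# ---- train / predict / evaluate ---------------------------------------------

label_index <- function(labels) ifelse(labels == "malignant", 1L, 0L)

#' Deterministic train/test split of a manifest by id hash
#'
#' @param df manifest data frame.
#' @param test_fraction fraction routed to the test split.
#' @return list with `train` and `test` data frames.
#' @export
split_manifest <- function(df, test_fraction = 0.2) {
  h <- vapply(df$id, str_hash31, numeric(1))
  # LCG avalanche rounds: the raw polynomial hash maps sequential ids to
  # consecutive values, which would route whole id blocks to one split
  for (r in 1:3) h <- (h * 69069 + 12345) %% 2147483647
  test <- (h %% 1000) < test_fraction * 1000
  list(train = df[!test, , drop = FALSE], test = df[test, , drop = FALSE])
}

#' Train the segmentation model
#'
#' Runs the full optimisation loop: augmented batches, the combined
#' cross-entropy + Dice + boundary-Dice (+ auxiliary classification) loss,
#' AdamW updates, the plateau learning-rate schedule and its stopping rule.
#' Prompts are teacher-forced with the ground-truth class during training.
#'
#' @param manifest path to a dataset manifest CSV.
#' @param cfg a [train_config()].
#' @param out_dir directory for checkpoints and the history CSV.
#' @param samples optional pre-loaded list of `sample_record`s (overrides
#'   `manifest`).
#' @param verbose print one line per epoch.
#' @return list: trained `model`, `history` data frame, `state`, paths of
#'   `checkpoint` (final) and `best_checkpoint`.
#' @export
train_model <- function(manifest, cfg = train_config(), out_dir = tempdir(),
                        samples = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(samples)) {
    df <- read_manifest(manifest)
    base <- dirname(manifest)
    samples <- lapply(seq_len(nrow(df)), function(i) load_sample(df[i, ], base))
  }
  n <- length(samples)
  if (n < 1L) stop("no training samples")
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  model <- build_model(cfg$model, seed = cfg$seed)
  enc_fp_before <- text_encoder_fingerprint(model)
  opt <- adamw(model$params, lr = cfg$lr_init, weight_decay = cfg$weight_decay)
  state <- init_train_state(cfg)
  history <- list()
  best_loss_seen <- Inf
  best_values <- NULL
  best_path <- file.path(out_dir, "model_best.rds")
  final_path <- file.path(out_dir, "model_final.rds")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  repeat {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    ep_terms <- c(l_ce = 0, l_dice = 0, l_boundary_dice = 0, l_cls = 0,
                  total = 0)
    nimg <- 0L
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      batch <- lapply(samples[take], augment_sample,
                      input_size = cfg$input_size, enabled = cfg$augment)
      imgs <- lapply(batch, `[[`, "image")
      B <- length(imgs)
      Hn <- cfg$input_size
      yflat <- matrix(unlist(lapply(batch, function(s) as.numeric(t(s$mask)))),
                      ncol = 1L)
      cls <- label_index(vapply(batch, `[[`, character(1), "label"))
      ag_tape_reset()
      fw <- model_forward(model, imgs, class_labels = cls, train = TRUE)
      ls <- ag_combined_loss(yflat, fw$prob, c(B, Hn, Hn), cls + 1L,
                             fw$logits, cfg$loss)
      if (!is.finite(val(ls$total))) {
        stop("training diverged (non-finite loss) at epoch ", state$epoch + 1L)
      }
      opt$zero_grad()
      ag_backward(ls$total)
      opt$lr <- state$lr
      opt$step()
      bd <- unlist(ls$breakdown)
      ep_terms <- ep_terms + bd[names(ep_terms)] * B
      nimg <- nimg + B
    }
    ep_terms <- ep_terms / nimg
    state <- lr_schedule_step(state, ep_terms[["total"]])
    history[[length(history) + 1L]] <-
      data.frame(epoch = state$epoch, l_ce = ep_terms[["l_ce"]],
                 l_dice = ep_terms[["l_dice"]],
                 l_boundary_dice = ep_terms[["l_boundary_dice"]],
                 l_cls = ep_terms[["l_cls"]], total = ep_terms[["total"]],
                 lr = state$lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.2e", state$epoch,
                      ep_terms[["total"]], state$lr))
    }
    if (ep_terms[["total"]] < best_loss_seen) {
      best_loss_seen <- ep_terms[["total"]]
      best_values <- lapply(model$params, function(p) p$v)
    }
    if (!is.null(cfg$target_mdice) && state$epoch %% cfg$check_every == 0L) {
      md <- training_mdice(model, samples)
      if (verbose) message(sprintf("  train mDice %.4f", md$mdice))
      if (md$mdice >= cfg$target_mdice) break
    }
    if (state$stop || state$epoch >= cfg$max_epochs) break
  }
  enc_fp_after <- text_encoder_fingerprint(model)
  if (!identical(enc_fp_before, enc_fp_after)) {
    stop("text encoder changed during training; it must stay frozen")
  }
  hist_df <- do.call(rbind, history)
  utils::write.csv(hist_df, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  save_checkpoint(model, final_path)
  if (!is.null(best_values)) {
    best_model <- list(cfg = model$cfg, params = lapply(names(best_values),
      function(nm) ag_param(best_values[[nm]], nm)),
      text_encoder = model$text_encoder, version = model$version)
    names(best_model$params) <- names(best_values)
    class(best_model) <- "fundusseg_model"
    save_checkpoint(best_model, best_path)
  } else {
    save_checkpoint(model, best_path)
  }
  list(model = model, history = hist_df, state = state,
       checkpoint = final_path, best_checkpoint = best_path)
}

#' Predict lesion masks and classes for images
#'
#' Inference uses the model's own predicted class for the prompt.
#'
#' @param model a trained `fundusseg_model`.
#' @param images list of `[3, H, W]` arrays (resized internally if not equal
#'   to a multiple of 32).
#' @param threshold probability cutoff for the binary masks.
#' @param force_class optional prompt-class override (ablation probe).
#' @return list per image: `prob` matrix, binary `mask`, `label`,
#'   `class_probs`; plus `resized` flag.
#' @export
predict_model <- function(model, images, threshold = 0.5, force_class = NULL) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  resized <- FALSE
  tgt <- model$cfg$input_size
  images <- lapply(images, function(im) {
    d <- dim(im)
    if (d[2] != tgt || d[3] != tgt) {
      resized <<- TRUE
      affine_warp(im, matrix(0, d[2], d[3]), tgt)$image
    } else im
  })
  out <- model_forward(model, images, train = FALSE, force_class = force_class)
  res <- lapply(seq_along(images), function(b) {
    pm <- out$prob_maps[[b]]
    list(prob = pm, mask = (pm >= threshold) * 1,
         label = model$cfg$class_names[out$pred_class[b] + 1L],
         class_probs = out$class_probs[b, ])
  })
  attr(res, "resized") <- resized
  res
}

#' Evaluate a model on a manifest
#'
#' @param model a trained model.
#' @param manifest manifest path or data frame.
#' @param base_dir directory of the manifest files (defaults to the manifest
#'   location).
#' @param threshold binarisation cutoff.
#' @param batch_size evaluation batch size.
#' @return an `eval_report` (see [evaluate_masks()]).
#' @export
evaluate_model <- function(model, manifest, base_dir = NULL, threshold = 0.5,
                           batch_size = 4L) {
  df <- if (is.data.frame(manifest)) manifest else read_manifest(manifest)
  if (is.null(base_dir)) {
    base_dir <- if (is.character(manifest)) dirname(manifest) else "."
  }
  if (nrow(df) < 1L) stop("empty manifest")
  preds <- list(); refs <- list()
  for (start in seq(1L, nrow(df), by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, nrow(df))
    ss <- lapply(rows, function(i) load_sample(df[i, ], base_dir))
    ss <- lapply(ss, augment_sample, input_size = model$cfg$input_size,
                 enabled = FALSE)
    pr <- predict_model(model, lapply(ss, `[[`, "image"), threshold)
    for (j in seq_along(rows)) {
      preds[[df$id[rows[j]]]] <- pr[[j]]$prob
      refs[[df$id[rows[j]]]] <- ss[[j]]$mask
    }
  }
  evaluate_masks(preds, refs, threshold)
}

#' Evaluate per-image training Dice of a model on in-memory samples
#' @keywords internal
training_mdice <- function(model, samples, threshold = 0.5) {
  ss <- lapply(samples, augment_sample, input_size = model$cfg$input_size,
               enabled = FALSE)
  pr <- predict_model(model, lapply(ss, `[[`, "image"), threshold)
  preds <- stats::setNames(lapply(pr, `[[`, "prob"),
                           vapply(ss, `[[`, character(1), "id"))
  refs <- stats::setNames(lapply(ss, `[[`, "mask"),
                          vapply(ss, `[[`, character(1), "id"))
  evaluate_masks(preds, refs, threshold)
}
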