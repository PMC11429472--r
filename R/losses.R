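# Training losses: pixel cross-entropy, Dice, and boundary Dice.
#
# The boundary Dice term restricts the Dice overlap to morphological boundary
# rings: each mask is (softly) dilated with an iterated window-max filter and
# the original is subtracted, leaving the one-structuring-element-wide outer
# ring.  Computing the ring as dilate(m) - m (rather than the reverse order,
# which is never positive) keeps the ring nonnegative; on binary masks it is
# exactly the outer boundary.  The window max keeps the term differentiable
# for continuous probability maps.

#' Loss configuration
#'
#' @param lambda1 weight of the pixel cross-entropy term.
#' @param lambda2 weight shared by the Dice and boundary-Dice terms.
#' @param lambda3 optional separate weight for the boundary-Dice term;
#'   defaults to `lambda2` (the two overlap terms share one weight).
#' @param lambda_cls weight of the auxiliary image-classification
#'   cross-entropy.
#' @param dilation_kernel odd window edge (>= 3) of the max-filter dilation.
#' @param dilation_iters number of dilation passes.
#' @param smooth_eps smoothing constant added to Dice numerators and
#'   denominators so empty masks are well defined.
#' @return a list of class `loss_config`.
#' @export
loss_config <- function(lambda1 = 1, lambda2 = 1, lambda3 = NULL,
                        lambda_cls = 1, dilation_kernel = 3L,
                        dilation_iters = 1L, smooth_eps = 1e-6) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda_cls >= 0,
            dilation_kernel %% 2L == 1L, dilation_kernel >= 3L,
            dilation_iters >= 1L, smooth_eps > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = if (is.null(lambda3)) lambda2 else lambda3,
                 lambda_cls = lambda_cls,
                 dilation_kernel = as.integer(dilation_kernel),
                 dilation_iters = as.integer(dilation_iters),
                 smooth_eps = smooth_eps),
            class = "loss_config")
}

check_same_shape <- function(y, p) {
  if (!identical(dim(y) %||% length(y), dim(p) %||% length(p))) {
    stop("y and p must have identical shape")
  }
}

#' Pixel-wise binary cross-entropy
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`, with `p` clipped to
#' `[eps, 1-eps]`.
#'
#' @param y binary reference mask (0/1).
#' @param p predicted probabilities in `[0, 1]`, same shape as `y`.
#' @param eps clipping constant.
#' @return nonnegative scalar.
#' @export
ce_loss <- function(y, p, eps = 1e-7) {
  check_same_shape(y, p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Dice loss
#'
#' `1 - (2 sum(y p) + eps) / (sum(y) + sum(p) + eps)`.
#'
#' @inheritParams ce_loss
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(y, p, eps = 1e-6) {
  check_same_shape(y, p)
  1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
}

#' Soft morphological dilation by an iterated window max
#'
#' On binary input this is dilation with a `kernel x kernel` square
#' structuring element; on continuous input it is a max filter, which keeps
#' downstream losses differentiable.  Output is elementwise `>=` input.
#'
#' @param x numeric matrix `[H, W]` with values in `[0, 1]`.
#' @param kernel odd window edge (>= 3).
#' @param iters number of passes.
#' @return matrix of the same shape.
#' @export
soft_dilate <- function(x, kernel = 3L, iters = 1L) {
  stopifnot(is.matrix(x), kernel %% 2L == 1L, kernel >= 3L, iters >= 1L)
  r <- kernel %/% 2L
  H <- nrow(x); W <- ncol(x)
  for (it in seq_len(iters)) {
    out <- x
    for (dy in -r:r) for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      ys <- seq_len(H) + dy
      xs <- seq_len(W) + dx
      oky <- ys >= 1L & ys <= H
      okx <- xs >= 1L & xs <= W
      sh <- matrix(0, H, W)
      sh[oky, okx] <- x[ys[oky], xs[okx], drop = FALSE]
      out <- pmax(out, sh)
    }
    x <- out
  }
  x
}

#' Boundary Dice loss
#'
#' Dice loss evaluated on the morphological boundary rings
#' `dilate(m) - m` of reference and prediction.
#'
#' @inheritParams ce_loss
#' @param cfg a [loss_config()].
#' @return scalar in `[0, 1]`.
#' @export
boundary_dice_loss <- function(y, p, cfg = loss_config()) {
  check_same_shape(y, p)
  stopifnot(is.matrix(y))
  yb <- soft_dilate(y, cfg$dilation_kernel, cfg$dilation_iters) - y
  pb <- soft_dilate(p, cfg$dilation_kernel, cfg$dilation_iters) - p
  dice_loss(yb, pb, cfg$smooth_eps)
}

#' Combined segmentation + classification loss
#'
#' `lambda1 * L_ce + lambda2 * L_dice + lambda3 * L_boundary_dice +
#'  lambda_cls * L_cls` where `L_cls` is the 2-class cross-entropy of the
#' auxiliary image classifier (omitted when `class_y` is `NULL`).
#'
#' @param y binary mask matrix.
#' @param p probability matrix.
#' @param class_y integer class index (1-based) or `NULL`.
#' @param class_p probability vector over classes or `NULL`.
#' @param cfg a [loss_config()].
#' @return list of class `loss_breakdown` with elements `l_ce`, `l_dice`,
#'   `l_boundary_dice`, `l_cls`, `total`.
#' @export
combined_loss <- function(y, p, class_y = NULL, class_p = NULL,
                          cfg = loss_config()) {
  l_ce <- ce_loss(y, p)
  l_dice <- dice_loss(y, p, cfg$smooth_eps)
  l_bd <- boundary_dice_loss(y, p, cfg)
  l_cls <- if (is.null(class_y)) 0 else {
    -log(pmin(pmax(class_p[class_y], 1e-12), 1))
  }
  terms <- c(l_ce = l_ce, l_dice = l_dice, l_boundary_dice = l_bd,
             l_cls = l_cls)
  if (any(!is.finite(terms))) {
    stop("non-finite loss term: ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  }
  total <- cfg$lambda1 * l_ce + cfg$lambda2 * l_dice + cfg$lambda3 * l_bd +
    cfg$lambda_cls * l_cls
  structure(list(l_ce = l_ce, l_dice = l_dice, l_boundary_dice = l_bd,
                 l_cls = l_cls, total = total), class = "loss_breakdown")
}

# ---- autodiff versions used by the training loop ----------------------------

# Dice loss between a constant mask column and a probability node [S, 1].
ag_dice_core <- function(ycol, pnode, eps) {
  num <- ag_addc(ag_mulc(ag_sum(ag_mulc(pnode, ycol)), 2), eps)
  den <- ag_addc(ag_sum(pnode), sum(ycol) + eps)
  ag_addc(ag_neg(ag_sdiv(num, den)), 1)
}

# Mean binary cross-entropy between constant y and probability node p.
ag_bce <- function(ycol, pnode, eps = 1e-7) {
  pv <- val(pnode)
  n <- length(pv)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  lossv <- -sum(ycol * log(pc) + (1 - ycol) * log(1 - pc)) / n
  ag_op(lossv, list(pnode), function(g) {
    inside <- (pv > eps) & (pv < 1 - eps)
    gp <- -(ycol / pc - (1 - ycol) / (1 - pc)) / n * inside
    list(matrix(g * gp, nrow(pv), 1L))
  })
}

# 2-class cross-entropy from logits [B, 2] against 1-based class indices.
ag_softmax_ce <- function(logits, class_idx) {
  lv <- val(logits)
  B <- nrow(lv)
  m <- lv - apply(lv, 1L, max)
  e <- exp(m)
  sm <- e / rowSums(e)
  picked <- sm[cbind(seq_len(B), class_idx)]
  lossv <- -mean(log(pmax(picked, 1e-12)))
  ag_op(lossv, list(logits), function(g) {
    onehot <- matrix(0, B, ncol(lv))
    onehot[cbind(seq_len(B), class_idx)] <- 1
    list(g * (sm - onehot) / B)
  })
}

# Combined loss on the tape.  yflat: constant mask column [S, 1];
# pnode: probability node; shp = c(B, H, W) for the dilation.
ag_combined_loss <- function(yflat, pnode, shp, class_idx, class_logits, cfg) {
  l_ce <- ag_bce(yflat, pnode)
  l_dice <- ag_dice_core(yflat, pnode, cfg$smooth_eps)
  ydil <- ag_no_grad(
    ag_maxfilter(yflat, shp[1], shp[2], shp[3],
                 cfg$dilation_kernel, cfg$dilation_iters))
  yb <- val(ydil) - yflat
  pb <- ag_sub(ag_maxfilter(pnode, shp[1], shp[2], shp[3],
                            cfg$dilation_kernel, cfg$dilation_iters), pnode)
  l_bd <- ag_dice_core(yb, pb, cfg$smooth_eps)
  l_cls <- if (is.null(class_idx)) NULL else ag_softmax_ce(class_logits, class_idx)
  total <- ag_add(ag_add(ag_mulc(l_ce, cfg$lambda1), ag_mulc(l_dice, cfg$lambda2)),
                  ag_mulc(l_bd, cfg$lambda3))
  if (!is.null(l_cls)) total <- ag_add(total, ag_mulc(l_cls, cfg$lambda_cls))
  vals <- c(l_ce = val(l_ce), l_dice = val(l_dice), l_boundary_dice = val(l_bd),
            l_cls = if (is.null(l_cls)) 0 else val(l_cls))
  if (any(!is.finite(vals))) {
    stop("non-finite loss term: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  list(total = total,
       breakdown = structure(as.list(c(vals, total = val(total))),
                             class = "loss_breakdown"))
}
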