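# The three-scale input pyramid.
#
# The network consumes one RGB image at three "scales": the image itself, and
# two lossless space-to-depth rearrangements that trade spatial resolution for
# channels (block 4 -> 48 channels at H/4, block 8 -> 192 channels at H/8).
# The 48-channel map is replicated channel-wise to 96 so its width matches the
# first convolutional stage of the medium-scale encoder branch.

#' Space-to-depth rearrangement of a CHW array
#'
#' Moves each `block x block` spatial tile into `block^2` channel slots:
#' `out[c*block^2 + u*block + v, i, j] == x[c, i*block + u, j*block + v]`
#' (zero-based indices).  The operation is a lossless bijection; see
#' [depth_to_space()] for its inverse.
#'
#' @param x numeric array `[C, H, W]`.
#' @param block integer block edge; `H` and `W` must be divisible by it.
#' @return numeric array `[C*block^2, H/block, W/block]`.
#' @export
#' @examples
#' x <- array(runif(3 * 8 * 8), c(3, 8, 8))
#' y <- space_to_depth(x, 4)
#' dim(y)  # 48 2 2
#' stopifnot(identical(depth_to_space(y, 4), x))
space_to_depth <- function(x, block) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  if (d[2] %% block != 0L || d[3] %% block != 0L) {
    stop(sprintf("spatial size %d x %d is not divisible by block %d",
                 d[2], d[3], block))
  }
  C <- d[1]; Ho <- d[2] %/% block; Wo <- d[3] %/% block
  out <- array(0, c(C * block * block, Ho, Wo))
  for (u in 0:(block - 1L)) for (v in 0:(block - 1L)) {
    out[(seq_len(C) - 1L) * block * block + u * block + v + 1L, , ] <-
      x[, (seq_len(Ho) - 1L) * block + u + 1L,
           (seq_len(Wo) - 1L) * block + v + 1L, drop = FALSE]
  }
  out
}

#' Inverse of [space_to_depth()]
#'
#' @param x numeric array `[C*block^2, h, w]`.
#' @param block integer block edge.
#' @return numeric array `[C, h*block, w*block]`.
#' @export
depth_to_space <- function(x, block) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  stopifnot(d[1] %% (block * block) == 0L)
  C <- d[1] %/% (block * block)
  out <- array(0, c(C, d[2] * block, d[3] * block))
  for (u in 0:(block - 1L)) for (v in 0:(block - 1L)) {
    out[, (seq_len(d[2]) - 1L) * block + u + 1L,
          (seq_len(d[3]) - 1L) * block + v + 1L] <-
      x[(seq_len(C) - 1L) * block * block + u * block + v + 1L, , , drop = FALSE]
  }
  out
}

#' Replicate channels of a CHW array to a target count
#'
#' Tiled replication: `out[c] == x[c mod C]`.  Used to widen the 48-channel
#' space-to-depth map to the 96 channels the medium-scale branch expects.
#'
#' @param x numeric array `[C, h, w]`.
#' @param target integer multiple of `C`.
#' @return numeric array `[target, h, w]`.
#' @export
replicate_channels <- function(x, target) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  C <- dim(x)[1]
  if (target %% C != 0L) {
    stop(sprintf("target %d is not a multiple of channel count %d", target, C))
  }
  out <- array(0, c(target, dim(x)[2], dim(x)[3]))
  for (c0 in seq_len(target)) out[c0, , ] <- x[(c0 - 1L) %% C + 1L, , ]
  out
}

#' Build the three-scale input pyramid
#'
#' @param image numeric array `[3, H, W]` with `H`, `W` divisible by 32.
#' @return an object of class `multiscale_input` with elements `I1`
#'   (`[3, H, W]`), `I2_raw` (`[48, H/4, W/4]`), `I2` (`[96, H/4, W/4]`,
#'   tiled replication of `I2_raw`) and `I3` (`[192, H/8, W/8]`).
#' @export
build_pyramid <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[1] == 3L)
  d <- dim(image)
  if (d[2] %% 32L != 0L || d[3] %% 32L != 0L) {
    stop(sprintf("image size %d x %d must be divisible by 32", d[2], d[3]))
  }
  I2_raw <- space_to_depth(image, 4L)
  structure(list(
    I1 = image,
    I2_raw = I2_raw,
    I2 = replicate_channels(I2_raw, 96L),
    I3 = space_to_depth(image, 8L)
  ), class = "multiscale_input")
}

# Convert a CHW array to the internal row layout [H*W, C] (raster order).
chw_to_rows <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(3L, 2L, 1L)), d[2] * d[3], d[1])
  m
}

# Inverse: [H*W, C] rows (raster order) back to a CHW array.
rows_to_chw <- function(m, H, W) {
  aperm(array(m, c(W, H, ncol(m))), c(3L, 2L, 1L))
}
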