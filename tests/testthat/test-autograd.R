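# Numerical gradient verification of the autodiff engine on the ops the
# network is built from.  Each check compares reverse-mode gradients against
# central finite differences on small random instances.

ag_check <- function(make_loss, params, tol = 1e-4) {
  pnodes <- lapply(params, ns$ag_param)
  ns$ag_tape_reset()
  loss <- make_loss(pnodes)
  ns$ag_backward(loss)
  for (nm in names(params)) {
    f <- function(x) {
      pn <- lapply(params, ns$ag_param)
      pn[[nm]]$v <- x
      ns$ag_no_grad(ns$val(make_loss(pn)))
    }
    ng <- num_grad(f, params[[nm]])
    got <- pnodes[[nm]]$g
    expect_false(is.null(got), label = paste("gradient of", nm))
    expect_lt(max(abs(ng - got)) / max(1, max(abs(ng))), tol)
  }
}

test_that("core dense ops backpropagate correctly", {
  set.seed(51)
  wr <- matrix(rnorm(8), 4, 2)
  ag_check(function(p) ns$ag_mean(ns$ag_relu(ns$ag_linear(p$x, p$W, p$b))),
           list(x = matrix(rnorm(12), 4, 3), W = matrix(rnorm(6), 3, 2),
                b = rnorm(2)))
  wl <- matrix(rnorm(20, 1), 4, 5)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_layernorm(p$x, p$g, p$b), wl)),
           list(x = matrix(rnorm(20), 4, 5), g = rnorm(5, 1, .1), b = rnorm(5)))
  ag_check(function(p) ns$ag_sum(ns$ag_gelu(p$x)),
           list(x = matrix(rnorm(10), 2, 5)))
})

test_that("spatial convolution ops backpropagate correctly", {
  set.seed(52)
  wt <- matrix(rnorm(24 * 3), 24, 3)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_dwconv(p$x, p$W, p$b, 2L, 3L, 4L, 3L), wt)),
           list(x = matrix(rnorm(72), 24, 3), W = matrix(rnorm(27), 9, 3),
                b = rnorm(3)))
  wt2 <- matrix(rnorm(144), 72, 2)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_convT(p$x, p$W, p$b, 2L, 3L, 3L, 2L), wt2)),
           list(x = matrix(rnorm(54), 18, 3), W = matrix(rnorm(54), 27, 2),
                b = rnorm(2)))
  wt4 <- matrix(rnorm(2 * 144 * 2), 288, 2)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_convT(p$x, p$W, p$b, 2L, 3L, 3L, 4L), wt4)),
           list(x = matrix(rnorm(54), 18, 3), W = matrix(rnorm(96), 48, 2),
                b = rnorm(2)))
  wt3 <- matrix(rnorm(48), 24, 2)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_conv3x3(p$x, p$W, p$b, 2L, 3L, 4L), wt3)),
           list(x = matrix(rnorm(72), 24, 3), W = matrix(rnorm(54), 27, 2),
                b = rnorm(2)))
})

test_that("attention, normalisation and head ops backpropagate correctly", {
  set.seed(53)
  mk <- array(0, c(4, 4, 2)); mk[1, 2, 2] <- -1e9; mk[2, 1, 2] <- -1e9
  wt <- matrix(rnorm(32), 8, 4)
  ag_check(function(p) {
    ns$ag_sum(ns$ag_mul(ns$ag_window_attention(p$qkv, 2L, 4L, 2L, p$pb,
                                               mk, c(1L, 2L)), wt))
  }, list(qkv = matrix(rnorm(96), 8, 12),
          pb = matrix(rnorm(32, 0, .3), 16, 2)))
  img <- rep(1:2, each = 6)
  wg <- matrix(rnorm(48), 12, 4)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_grn(p$x, p$g, p$b, img), wg)),
           list(x = matrix(rnorm(48), 12, 4), g = rnorm(4, 0, .5), b = rnorm(4)))
  img2 <- rep(1:2, each = 5)
  wh <- matrix(rnorm(10), 10, 1)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_dynhead(p$F, p$P, img2), wh)),
           list(F = matrix(rnorm(30), 10, 3),
                P = matrix(rnorm(226, 0, .5), 2, 113)))
  wm <- matrix(rnorm(16), 16, 1)
  ag_check(function(p) ns$ag_sum(ns$ag_mul(ns$ag_maxfilter(p$x, 1L, 4L, 4L, 3L, 1L), wm)),
           list(x = matrix(runif(16), 16, 1)))
})

test_that("gradients accumulate across shared uses and eval mode records nothing", {
  x <- ns$ag_param(matrix(1:4, 2, 2) * 1.0)
  ns$ag_tape_reset()
  y <- ns$ag_add(ns$ag_mulc(x, 2), ns$ag_mulc(x, 3))   # 5x
  ns$ag_backward(ns$ag_sum(y))
  expect_equal(x$g, matrix(5, 2, 2))
  out <- ns$ag_no_grad(ns$ag_mulc(x, 2))
  expect_false(ns$is_node(out))
})
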