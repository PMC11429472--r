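test_that("cross-entropy matches hand values and the scalar-loop oracle", {
  expect_equal(ce_loss(matrix(1), matrix(0.5)), log(2), tolerance = 1e-9)
  y0 <- matrix(c(1, 0), 1, 2)
  p0 <- matrix(c(1 - 1e-7, 1e-7), 1, 2)
  expect_lt(ce_loss(y0, p0), 1e-6)
  set.seed(4)
  for (i in 1:100) {
    y <- matrix(rbinom(25, 1, 0.4), 5, 5)
    p <- matrix(runif(25), 5, 5)
    expect_equal(ce_loss(y, p), oracle_ce(y, p), tolerance = 1e-12)
  }
})

test_that("Dice loss matches hand values, the oracle, and its identities", {
  y <- matrix(c(1, 0), 1, 2)
  expect_equal(dice_loss(y, matrix(c(0.5, 0.5), 1, 2)), 0.5, tolerance = 1e-6)
  yb <- matrix(rbinom(25, 1, 0.5), 5, 5)
  expect_lt(dice_loss(yb, yb), 1e-6)
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, z), 0)           # empty-mask convention (smoothed)
  set.seed(5)
  for (i in 1:100) {
    yy <- matrix(rbinom(25, 1, 0.4), 5, 5)
    pp <- matrix(runif(25), 5, 5)
    expect_equal(dice_loss(yy, pp), oracle_dice_loss(yy, pp), tolerance = 1e-12)
  }
})

test_that("soft dilation equals brute-force window max", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  d <- soft_dilate(m, 3L)
  expect_identical(sum(d), 9)                 # 3x3 block of ones
  expect_identical(d[2:4, 2:4], matrix(1, 3, 3))
  ones <- matrix(1, 4, 4)
  expect_identical(soft_dilate(ones, 3L), ones)
  set.seed(6)
  for (i in 1:100) {
    x <- matrix(runif(36), 6, 6)
    expect_equal(soft_dilate(x, 3L), oracle_dilate(x, 3L), tolerance = 1e-12)
    expect_true(all(soft_dilate(x, 3L) >= x))
  }
  x <- matrix(runif(36), 6, 6)
  expect_equal(soft_dilate(x, 3L, iters = 2L), oracle_dilate(x, 3L, iters = 2L))
  expect_equal(soft_dilate(x, 5L), oracle_dilate(x, 5L))
})

test_that("boundary Dice vanishes on identical masks and matches the ring oracle", {
  set.seed(7)
  y <- matrix(rbinom(36, 1, 0.4), 6, 6)
  expect_lt(boundary_dice_loss(y, y), 1e-6)
  # 2x2 block centred in 6x6 against an all-zero prediction: the reference
  # ring has 12 pixels, the prediction ring is empty -> loss near 1
  yb <- matrix(0, 6, 6); yb[3:4, 3:4] <- 1
  ring <- soft_dilate(yb, 3L) - yb
  expect_identical(sum(ring), 12)
  expect_gt(boundary_dice_loss(yb, matrix(0, 6, 6)), 1 - 1e-5)
  ones <- matrix(1, 6, 6)
  expect_equal(boundary_dice_loss(ones, ones), 0)
  for (i in 1:100) {
    yy <- matrix(rbinom(36, 1, 0.4), 6, 6)
    pp <- matrix(runif(36), 6, 6)
    expect_equal(boundary_dice_loss(yy, pp), oracle_boundary_dice(yy, pp),
                 tolerance = 1e-10)
  }
})

test_that("the combined loss recomposes exactly from its terms", {
  set.seed(8)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64), 8, 8)
  cp <- c(0.3, 0.7)
  for (l1 in c(1, 0.5)) for (l2 in c(1, 0.5, 0)) {
    cfg <- loss_config(lambda1 = l1, lambda2 = l2)
    bd <- combined_loss(y, p, class_y = 2L, class_p = cp, cfg = cfg)
    expect_equal(bd$total,
                 l1 * bd$l_ce + l2 * bd$l_dice + l2 * bd$l_boundary_dice +
                   bd$l_cls, tolerance = 1e-12)
  }
  # lambda2 = 0 reduces to cross-entropy (+ classifier)
  cfg0 <- loss_config(lambda2 = 0)
  bd0 <- combined_loss(y, p, class_y = 1L, class_p = cp, cfg = cfg0)
  expect_equal(bd0$total, bd0$l_ce + bd0$l_cls, tolerance = 1e-12)
  # halving lambda2 halves the overlap contribution exactly
  b1 <- combined_loss(y, p, cfg = loss_config(lambda2 = 1))
  b2 <- combined_loss(y, p, cfg = loss_config(lambda2 = 0.5))
  expect_equal(b2$total - b2$l_ce, (b1$total - b1$l_ce) / 2, tolerance = 1e-12)
  # perfect prediction leaves only the classifier term
  bp <- combined_loss(y, y, class_y = 1L, class_p = c(0.9, 0.1))
  expect_lt(bp$total - bp$l_cls, 1e-5)
  # every ablation row of the loss table is reachable through the config
  cfgs <- list(loss_config(lambda2 = 0),
               loss_config(lambda2 = 1, lambda3 = 0),
               loss_config(lambda2 = 0, lambda3 = 1),
               loss_config())
  expect_length(unique(vapply(cfgs, function(cf) {
    combined_loss(y, p, cfg = cf)$total
  }, numeric(1))), 4L)
  expect_error(loss_config(dilation_kernel = 4L))
})

test_that("tape losses agree with the plain implementations and are differentiable", {
  set.seed(9)
  B <- 1L; H <- 6L; W <- 6L
  y <- matrix(rbinom(36, 1, 0.4), H, W)
  yflat <- matrix(as.numeric(t(y)), ncol = 1)
  z0 <- matrix(rnorm(36), 36, 1)
  zn <- ns$ag_param(z0)
  ns$ag_tape_reset()
  p <- ns$ag_sigmoid(zn)
  ls <- ns$ag_combined_loss(yflat, p, c(B, H, W), 1L,
                            ns$ag_param(matrix(c(0.2, -0.1), 1, 2)),
                            loss_config())
  pm <- matrix(ns$val(p)[, 1], H, W, byrow = TRUE)
  expect_equal(ls$breakdown$l_ce, ce_loss(y, pm), tolerance = 1e-10)
  expect_equal(ls$breakdown$l_dice, dice_loss(y, pm), tolerance = 1e-10)
  expect_equal(ls$breakdown$l_boundary_dice, boundary_dice_loss(y, pm),
               tolerance = 1e-10)
  ns$ag_backward(ls$total)
  g <- zn$g
  # finite differences on the segmentation part of the loss
  f <- function(zv) {
    pv <- 1 / (1 + exp(-zv))
    pmv <- matrix(pv[, 1], H, W, byrow = TRUE)
    cl <- combined_loss(y, pmv, class_y = 1L, class_p = c(0.57, 0.43))
    cl$l_ce + cl$l_dice + cl$l_boundary_dice
  }
  idx <- sample(36, 10)
  for (i in idx) {
    zp <- z0; zp[i] <- zp[i] + 1e-5
    zm <- z0; zm[i] <- zm[i] - 1e-5
    fd <- (f(zp) - f(zm)) / 2e-5
    expect_equal(g[i], fd, tolerance = 1e-3)
  }
})
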