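test_that("global average pooling reduces each channel to its mean", {
  x <- array(0.3, c(4, 3, 3))
  expect_equal(gap_chw(x), rep(0.3, 4))
  x2 <- array(0, c(2, 2, 2))
  x2[1, , ] <- matrix(c(1, 3, 5, 7), 2, 2)
  expect_equal(gap_chw(x2)[1], 4)
  big <- array(rnorm(768 * 2 * 2), c(768, 2, 2))
  expect_length(gap_chw(big), 768L)
})

test_that("the SE gate matches the per-channel brute-force oracle", {
  set.seed(13)
  # zero gate halves the input; zero input stays zero
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(se_gate(x, matrix(0, 4, 4), rep(0, 4)), 0.5 * x,
               tolerance = 1e-12)
  expect_equal(se_gate(array(0, c(4, 2, 2)), matrix(rnorm(16), 4, 4),
                       rnorm(4)),
               array(0, c(4, 2, 2)))
  for (i in 1:100) {
    C <- sample(2:8, 1)
    h <- sample(2:5, 1); w <- sample(2:5, 1)
    xx <- array(rnorm(C * h * w), c(C, h, w))
    W <- matrix(rnorm(C * C, 0, 0.5), C, C)
    b <- rnorm(C)
    got <- se_gate(xx, W, b)
    expect_equal(got, oracle_se_gate(xx, W, b), tolerance = 1e-10)
    # attenuation: gating never amplifies
    expect_true(all(abs(got) <= abs(xx) + 1e-12))
    expect_true(all(abs(got) < abs(xx) | xx == 0))
  }
})

test_that("fusion adds the gated side features to the centre features", {
  set.seed(14)
  C <- 6L
  F1 <- array(rnorm(C * 4), c(C, 2, 2))
  z <- array(0, c(C, 2, 2))
  g <- list(W = matrix(rnorm(C * C, 0, .3), C, C), b = rnorm(C))
  expect_equal(fuse_features(F1, z, z, g, g), F1, tolerance = 1e-12)
  # saturated gate (huge bias) passes the side branches through unchanged
  gsat <- list(W = matrix(0, C, C), b = rep(50, C))
  F2 <- array(rnorm(C * 4), c(C, 2, 2))
  F3 <- array(rnorm(C * 4), c(C, 2, 2))
  expect_equal(fuse_features(F1, F2, F3, gsat, gsat), F1 + F2 + F3,
               tolerance = 1e-9)
  # random instance equals the oracle composition
  g2 <- list(W = matrix(rnorm(C * C, 0, .3), C, C), b = rnorm(C))
  g3 <- list(W = matrix(rnorm(C * C, 0, .3), C, C), b = rnorm(C))
  expect_equal(fuse_features(F1, F2, F3, g2, g3),
               F1 + oracle_se_gate(F2, g2$W, g2$b) +
                 oracle_se_gate(F3, g3$W, g3$b), tolerance = 1e-10)
  expect_error(fuse_features(F1, F2, array(0, c(C, 3, 2)), g2, g3))
})

test_that("the model's internal fusion agrees with the array-level functions", {
  m <- micro_model()
  img <- micro_samples(1)[[1]]$image
  enc <- encode_pyramid(m, img)
  g2 <- list(W = ns$val(m$params[["fuse.g2W"]]), b = ns$val(m$params[["fuse.g2b"]]))
  g3 <- list(W = ns$val(m$params[["fuse.g3W"]]), b = ns$val(m$params[["fuse.g3b"]]))
  expected <- fuse_features(enc$F1, enc$F2, enc$F3, g2, g3)
  fw <- model_forward(m, img)
  got <- ns$rows_to_chw(ns$val(fw$F), 2L, 2L)
  expect_equal(got, expected, tolerance = 1e-9)
})
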