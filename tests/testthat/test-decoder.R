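test_that("decoder blocks follow the channel plan and exact shape chain", {
  cfg <- micro_cfg()
  expect_identical(cfg$decoder_channels,
                   c(cfg$stage_channels[3], cfg$stage_channels[2],
                     cfg$stage_channels[1], 3L))
  # full-scale plan is 384, 192, 96, 3
  expect_identical(model_config(input_size = 448L)$decoder_channels,
                   c(384L, 192L, 96L, 3L))
  m <- micro_model()
  # parameter shapes pin the per-block widths
  dc <- cfg$decoder_channels
  cin <- c(cfg$stage_channels[4], dc[1], dc[2], dc[3])
  for (i in 1:4) {
    expect_identical(dim(ns$val(m$params[[sprintf("dec%d.c1W", i)]])),
                     c(cin[i], dc[i]))
    expect_identical(dim(ns$val(m$params[[sprintf("dec%d.c2W", i)]])),
                     c(dc[i], dc[i]))
  }
  fw <- model_forward(m, micro_samples(1)[[1]]$image)
  expect_identical(dim(ns$val(fw$Fp)), c(64L * 64L, 3L))
})

test_that("transposed convolutions upsample exactly and zero weights give zero", {
  set.seed(15)
  # stride 2: 3x3 kernel; output is exactly 2H x 2W
  x <- matrix(rnorm(6 * 6 * 4), 36, 4)
  W <- matrix(rnorm(9 * 4 * 2, 0, .3), 36, 2)
  b <- rnorm(2)
  y <- ns$ag_convT(x, W, b, 1L, 6L, 6L, 2L)
  expect_identical(dim(y), c(144L, 2L))
  y0 <- ns$ag_convT(x, matrix(0, 36, 2), c(0, 0), 1L, 6L, 6L, 2L)
  expect_true(all(y0 == 0))
  # stride 4: every output pixel receives exactly one kernel contribution
  W4 <- matrix(0, 16 * 4, 1); W4[seq(1, 61, by = 4), 1] <- 1  # channel-1 taps
  y4 <- ns$ag_convT(x, W4, 0, 1L, 6L, 6L, 4L)
  expect_identical(dim(y4), c(576L, 1L))
  # each input value appears 16 times (painted over its 4x4 block)
  expect_equal(sort(unique(round(y4, 10))), sort(unique(round(x[, 1], 10))))
  expect_equal(sum(y4), 16 * sum(x[, 1]), tolerance = 1e-9)
})

test_that("zeroing skip projections changes the decoded output", {
  cfg <- model_config(input_size = 64L, micro_scale = 4L)
  m1 <- build_model(cfg, seed = 21L)
  img <- micro_samples(1)[[1]]$image
  base <- model_forward(m1, img)$prob_maps[[1]]
  for (i in 1:3) {
    m1$params[[sprintf("skip%d.W", i)]]$v[] <- 0
    m1$params[[sprintf("skip%d.b", i)]]$v[] <- 0
  }
  ablated <- model_forward(m1, img)$prob_maps[[1]]
  expect_gt(max(abs(base - ablated)), 0)
})

test_that("skip projections are sized for the branches present at each resolution", {
  m <- micro_model()
  sc <- micro_cfg()$stage_channels
  # H/16 and H/8: all three branches contribute; H/4: only two
  expect_identical(nrow(ns$val(m$params[["skip1.W"]])), 3L * sc[3])
  expect_identical(nrow(ns$val(m$params[["skip2.W"]])), 3L * sc[2])
  expect_identical(nrow(ns$val(m$params[["skip3.W"]])), 2L * sc[1])
  # single-branch variant: one map per resolution
  cfg1 <- model_config(input_size = 64L, micro_scale = 4L,
                       encoder_variant = "swin_only")
  m1 <- build_model(cfg1, seed = 1L)
  expect_identical(nrow(ns$val(m1$params[["skip1.W"]])), sc[3])
})
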