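test_that("the three branches emit identically shaped final maps", {
  m <- micro_model()
  img <- micro_samples(1)[[1]]$image
  enc <- encode_pyramid(m, img)
  C4 <- m$cfg$stage_channels[4]
  expect_identical(dim(enc$F1), c(C4, 2L, 2L))
  expect_identical(dim(enc$F2), dim(enc$F1))
  expect_identical(dim(enc$F3), dim(enc$F1))
  # stage ladders: halving spatial sizes, configured channels
  sm <- enc$stage_maps
  expect_identical(dim(sm$b1[["1"]]), c(m$cfg$stage_channels[1], 16L, 16L))
  expect_identical(dim(sm$b1[["3"]]), c(m$cfg$stage_channels[3], 4L, 4L))
  expect_identical(dim(sm$b2[["1"]]), c(m$cfg$stage_channels[1], 16L, 16L))
  # the small-scale branch starts at H/8 and has only three stage maps
  expect_identical(sort(names(sm$b3)), c("2", "3", "4"))
  expect_identical(dim(sm$b3[["2"]]), c(m$cfg$stage_channels[2], 8L, 8L))
})

test_that("branch forwards are deterministic in eval mode", {
  m <- micro_model()
  img <- micro_samples(1)[[1]]$image
  f1 <- model_forward(m, img)
  f2 <- model_forward(m, img)
  expect_identical(f1$prob_maps[[1]], f2$prob_maps[[1]])
  expect_identical(f1$class_probs, f2$class_probs)
})

test_that("swapping the centre branch and single-branch variants all build and run", {
  for (variant in list(list(encoder_variant = "multiscale",
                            center_branch = "convnext"),
                       list(encoder_variant = "swin_only"),
                       list(encoder_variant = "convnext_only"),
                       list(encoder_variant = "resnet50_only"))) {
    cfg <- do.call(model_config,
                   c(list(input_size = 64L, micro_scale = 4L), variant))
    mm <- build_model(cfg, seed = 4L)
    fw <- model_forward(mm, array(runif(3 * 64 * 64), c(3, 64, 64)))
    expect_identical(dim(fw$prob_maps[[1]]), c(64L, 64L))
    expect_true(all(fw$prob_maps[[1]] > 0 & fw$prob_maps[[1]] < 1))
  }
})

test_that("full-size branch parameter counts sit near the Tiny reference models", {
  cfg <- model_config(input_size = 448L)
  m <- build_model(cfg, seed = 0L)
  swin_n <- ns$model_param_count(m, "b1.")
  conv_n <- ns$model_param_count(m, "b2.")
  expect_lt(abs(swin_n - 28.3e6) / 28.3e6, 0.15)   # attention-branch budget
  expect_lt(abs(conv_n - 28.6e6) / 28.6e6, 0.15)   # conv-branch budget
  rm(m); gc()
})

test_that("one training step moves every module including all three branches", {
  ss <- micro_samples(2)
  mcfg <- model_config(input_size = 64L, micro_scale = 4L)
  tc <- train_config(input_size = 64L, batch_size = 2L, max_epochs = 1L,
                     augment = FALSE, model = mcfg, seed = 1L)
  m <- build_model(mcfg, seed = 1L)
  imgs <- lapply(ss, `[[`, "image")
  yflat <- matrix(unlist(lapply(ss, function(s) as.numeric(t(s$mask)))),
                  ncol = 1L)
  cls <- ifelse(vapply(ss, `[[`, character(1), "label") == "malignant", 1L, 0L)
  ns$ag_tape_reset()
  fw <- model_forward(m, imgs, class_labels = cls, train = TRUE)
  ls <- ns$ag_combined_loss(yflat, fw$prob, c(2L, 64L, 64L), cls + 1L,
                            fw$logits, loss_config())
  ns$ag_backward(ls$total)
  gnorm <- function(prefix) {
    nm <- names(m$params)[startsWith(names(m$params), prefix)]
    sum(vapply(m$params[nm], function(p) {
      if (is.null(p$g)) 0 else sum(p$g^2)
    }, numeric(1)))
  }
  for (pfx in c("b1.", "b2.", "b3.", "fuse.", "dec1.", "dec4.", "skip1.",
                "cont.", "cls.")) {
    expect_gt(gnorm(pfx), 0)
  }
})
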