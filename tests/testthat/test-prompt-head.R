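test_that("the prompt template fills verbatim and rejects bad classes", {
  tp <- prompt_template()
  expect_identical(fill_prompt(tp, 0L), "it is a image of benign tumor")
  expect_identical(fill_prompt(tp, 1L), "it is a image of malignant tumor")
  expect_false(grepl("{", fill_prompt(tp, 0L), fixed = TRUE))
  expect_error(fill_prompt(tp, 2L), "out of range")
})

test_that("the hash text encoder is deterministic, unit norm, and class separating", {
  v1 <- hash_text_encoder("it is a image of benign tumor")
  v2 <- hash_text_encoder("it is a image of benign tumor")
  v3 <- hash_text_encoder("it is a image of malignant tumor")
  expect_identical(v1, v2)
  expect_length(v1, 512L)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-6)
  expect_lt(sum(v1 * v3), 1 - 1e-3)       # cosine similarity below 1
  # token order matters
  expect_false(isTRUE(all.equal(hash_text_encoder("benign tumor"),
                                hash_text_encoder("tumor benign"))))
  expect_error(make_text_encoder("clip"), "CLIP")
  expect_true(make_text_encoder("hash")$frozen)
})

test_that("the classifier head produces a probability distribution", {
  m <- micro_model()
  C4 <- m$cfg$stage_channels[4]
  Fm <- array(rnorm(C4 * 2 * 2), c(C4, 2, 2))
  pr <- classify_features(m, Fm)
  expect_length(pr, 2L)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # zero classifier weights give a uniform distribution
  m0 <- build_model(micro_cfg(), seed = 2L)
  m0$params[["cls.W1"]]$v[] <- 0
  m0$params[["cls.b1"]]$v[] <- 0
  m0$params[["cls.W2"]]$v[] <- 0
  expect_equal(classify_features(m0, Fm), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("the controller emits a 113-vector that splits into the head layers", {
  expect_identical(ns$dynhead_param_length(), 113L)
  m <- micro_model()
  proF <- rnorm(m$cfg$stage_channels[4] + 512)
  p <- controller_forward(m, proF)
  expect_length(p, 113L)
  ly <- ns$dynhead_split(p)
  expect_identical(dim(ly[[1]]$W), c(3L, 8L))
  expect_identical(dim(ly[[2]]$W), c(8L, 8L))
  expect_identical(dim(ly[[3]]$W), c(8L, 1L))
  # zero controller weights and biases collapse the output to zero
  m0 <- build_model(micro_cfg(), seed = 3L)
  for (nm in c("cont.W1", "cont.b1", "cont.W2", "cont.b2", "cont.W3", "cont.b3")) {
    m0$params[[nm]]$v[] <- 0
  }
  expect_identical(max(abs(controller_forward(m0, proF))), 0)
  # different prompt embeddings change the generated parameters
  e0 <- hash_text_encoder("it is a image of benign tumor")
  e1 <- hash_text_encoder("it is a image of malignant tumor")
  gapF <- rnorm(m$cfg$stage_channels[4])
  expect_gt(max(abs(controller_forward(m, c(gapF, e0)) -
                      controller_forward(m, c(gapF, e1)))), 0)
})

test_that("the dynamic head matches a per-pixel oracle and stays in (0,1)", {
  set.seed(12)
  for (i in 1:100) {
    Fp <- array(rnorm(3 * 3 * 1), c(3, 3, 1))   # 3-pixel toy map
    params <- rnorm(113, 0, 0.7)
    out <- apply_dynamic_head(Fp, params)
    expect_equal(out, oracle_dynhead(Fp, params), tolerance = 1e-10)
    expect_true(all(out > 0 & out < 1))
  }
  # all-zero parameters give the sigmoid midpoint everywhere
  Fp <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  expect_identical(unique(as.numeric(apply_dynamic_head(Fp, rep(0, 113)))), 0.5)
  # the internal batched op agrees with the array-level head
  params <- rnorm(113, 0, 0.5)
  rows <- ns$chw_to_rows(Fp)
  pm <- ns$ag_dynhead(rows, matrix(params, 1), rep(1L, 16))
  expect_equal(matrix(pm[, 1], 4, 4, byrow = TRUE),
               apply_dynamic_head(Fp, params), tolerance = 1e-12)
})

test_that("swapping the class prompt changes the predicted mask", {
  m <- micro_model()
  img <- micro_samples(1)[[1]]$image
  out0 <- predict_model(m, list(img), force_class = 0L)
  out1 <- predict_model(m, list(img), force_class = 1L)
  expect_gt(max(abs(out0[[1]]$prob - out1[[1]]$prob)), 0)
})
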