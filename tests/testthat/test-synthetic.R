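test_that("generated lesions respect the configured area range and are deterministic", {
  cfg <- synth_config(image_size = 64L, n_images = 4L, seed = 1L)
  s <- generate_sample(cfg, 0L)
  frac <- s$lesion_area / (64 * 64)
  expect_gte(frac, cfg$lesion_area_fraction_range[1])
  expect_lte(frac, cfg$lesion_area_fraction_range[2])
  expect_true(all(s$mask %in% c(0, 1)))
  expect_identical(s$lesion_area, sum(s$mask))
  expect_identical(dim(s$image), c(3L, 64L, 64L))
  s2 <- generate_sample(cfg, 0L)
  expect_identical(s$image, s2$image)
  expect_identical(s$mask, s2$mask)
  expect_identical(s$label, s2$label)
})

test_that("each sample holds one connected lesion and area control holds across samples", {
  cfg <- synth_config(image_size = 64L, n_images = 40L, seed = 3L)
  fr <- numeric(40)
  for (i in 0:39) {
    s <- generate_sample(cfg, i)
    fr[i + 1] <- s$lesion_area / (64 * 64)
    if (i < 12) expect_identical(count_components(s$mask), 1L)
  }
  expect_true(all(fr >= cfg$lesion_area_fraction_range[1]))
  expect_true(all(fr <= cfg$lesion_area_fraction_range[2]))
})

test_that("lesion areas span at least a 10-fold range across a large draw", {
  cfg <- synth_config(image_size = 64L, n_images = 200L, seed = 9L)
  areas <- vapply(0:199, function(i) generate_sample(cfg, i)$lesion_area,
                  numeric(1))
  expect_gte(max(areas) / min(areas), 10)
})

test_that("empirical benign fraction matches the configured probability", {
  cfg <- synth_config(image_size = 32L, n_images = 1000L, seed = 7L)
  labs <- vapply(0:999, function(i) generate_sample(cfg, i)$label, character(1))
  expect_lt(abs(mean(labs == "benign") - 0.4055), 0.05)
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(lesion_area_fraction_range = c(0.3, 0.2)))
  expect_error(synth_config(image_size = 16L,
                            lesion_area_fraction_range = c(0.001, 0.27)),
               "9 pixels")
  expect_error(synth_config(benign_fraction = 1.5))
})

test_that("dataset generation writes PNGs that round-trip exactly", {
  cfg <- synth_config(image_size = 64L, n_images = 8L, seed = 2L)
  out <- withr::local_tempdir()
  mf <- generate_dataset(cfg, out)
  df <- read_manifest(mf)
  expect_identical(nrow(df), 8L)
  expect_length(list.files(out, pattern = "\\.png$"), 16L)
  for (i in c(1L, 5L)) {
    back <- load_sample(df[i, ], out)
    orig <- generate_sample(cfg, i - 1L)
    expect_equal(back$image, orig$image, tolerance = 1e-9)
    expect_identical(back$mask, orig$mask)
    expect_identical(back$label, orig$label)
  }
})

test_that("manifest summary reproduces class percentages", {
  df <- data.frame(id = sprintf("s%03d", 1:254),
                   image_path = "x.png", mask_path = "y.png",
                   label = c(rep("benign", 103), rep("malignant", 151)))
  sm <- summarize_manifest(df)
  expect_identical(sm$percentage[sm$label == "benign"], 40.55)
  expect_identical(sm$percentage[sm$label == "malignant"], 59.45)
  sm2 <- summarize_manifest(data.frame(id = c("a", "b"), image_path = "x",
                                       mask_path = "y",
                                       label = c("benign", "malignant")))
  expect_identical(sm2$percentage, c(50, 50))
  sm3 <- summarize_manifest(data.frame(id = letters[1:5], image_path = "x",
                                       mask_path = "y", label = "malignant"))
  expect_identical(sm3$percentage, c(0, 100))
  bad <- data.frame(id = c("a", "b"), image_path = "x", mask_path = "y",
                    label = c("benign", "cyst"))
  expect_error(summarize_manifest(bad), "cyst")
})
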