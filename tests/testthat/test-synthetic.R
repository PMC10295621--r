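# Synthetic data: determinism, constraint enforcement, augmentation
# consistency, folder I/O.

test_that("generator is a pure function of its configuration", {
  cfg <- gen_config(n_samples = 3, image_size = c(64, 64), seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(gen_config(n_samples = 3, image_size = c(64, 64),
                                    seed = 43))
  expect_false(identical(d1, d3))
})

test_that("samples satisfy the configured constraints", {
  cfg <- gen_config(n_samples = 12, image_size = c(64, 64),
                    lesion_area_range = c(0.05, 0.30), seed = 7)
  ds <- generate_dataset(cfg)
  for (s in ds) {
    expect_equal(dim(s$image), c(3, 64, 64))
    expect_equal(dim(s$mask), c(1, 64, 64))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0, 1)))         # strictly binary
    frac <- mean(s$mask)
    expect_gte(frac, 0.05); expect_lte(frac, 0.30)
  }
})

test_that("lesion contrast dominates the noise (Monte Carlo)", {
  # contrast lower bound > 2 * noise sigma implies a clearly separated
  # foreground mean in expectation
  cfg <- gen_config(n_samples = 40, image_size = c(48, 48),
                    contrast_range = c(0.25, 0.55), noise_sigma = 0.05,
                    hair_occluders = 0L, seed = 9)
  ds <- generate_dataset(cfg)
  gaps <- vapply(ds, function(s) {
    fg <- as.vector(s$mask[1, , ] == 1)
    im <- matrix(s$image, nrow = 3)
    abs(mean(im[, fg]) - mean(im[, !fg]))
  }, 0)
  expect_gt(mean(gaps), cfg$noise_sigma)
  expect_gt(mean(gaps > cfg$noise_sigma), 0.9)
})

test_that("augmentation: identity draw, binary masks, geometric consistency", {
  cfg <- gen_config(n_samples = 1, image_size = c(64, 64), seed = 5)
  s <- generate_dataset(cfg)[[1]]
  neutral <- list(angle = 0, zoom = 1, crop_frac = 1, crop_cx = 0,
                  crop_cy = 0, brightness = 0, contrast = 1)
  id <- augment(s, params = neutral)
  expect_equal(id$image, s$image, tolerance = 1e-6)
  expect_equal(id$mask, s$mask)
  # any draw keeps the mask binary with unchanged shape
  a <- augment(s, seed = 1)
  expect_equal(dim(a$mask), dim(s$mask))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_identical(augment(s, seed = 1)$mask, a$mask)  # seeded determinism
  # 90-degree rotation of a centred square preserves mask area within 2%
  sq <- list(image = array(0.5, dim = c(3, 64, 64)),
             mask = array(0, dim = c(1, 64, 64)))
  sq$mask[1, 25:40, 25:40] <- 1
  rot <- augment(sq, params = modifyList(neutral, list(angle = 90)))
  expect_lt(abs(sum(rot$mask) - sum(sq$mask)) / sum(sq$mask), 0.02)
  # image and mask receive the same geometric transform: transform a
  # sample whose image equals its mask and compare the two outputs
  mimg <- list(image = aperm(array(rep(sq$mask[1, , ], 3),
                                   dim = c(64, 64, 3)), c(3, 1, 2)),
               mask = sq$mask)
  tw <- augment(mimg, params = modifyList(neutral,
                                          list(angle = 17, zoom = 1.1)))
  agree <- mean((tw$image[1, , ] >= 0.5) == (tw$mask[1, , ] == 1))
  expect_gt(agree, 0.97)   # bilinear vs nearest resampling differ at edges
})

test_that("folder round trip is lossless and pairing errors are explicit", {
  cfg <- gen_config(n_samples = 4, image_size = c(64, 64), seed = 3)
  ds <- generate_dataset(cfg)
  root <- file.path(tempdir(), "lcm_synth_test")
  unlink(root, recursive = TRUE)
  save_folder(ds, root)
  back <- load_folder(root, size = 64)
  for (i in seq_along(ds)) {
    expect_equal(back[[i]]$mask, ds[[i]]$mask)
    expect_equal(back[[i]]$image, round(ds[[i]]$image * 255) / 255,
                 tolerance = 1e-9)
  }
  # resize path: save at 64, load at 32
  resized <- load_folder(root, size = 32)
  expect_equal(dim(resized[[1]]$image), c(3, 32, 32))
  expect_true(all(resized[[1]]$mask %in% c(0, 1)))
  # missing mask is reported with the stem
  file.remove(file.path(root, "masks", "sample_0002.png"))
  expect_error(load_folder(root, size = 64), "sample_0002")
  unlink(root, recursive = TRUE)
})

test_that("train/test split is disjoint, exhaustive and seed-stable", {
  cfg <- gen_config(n_samples = 10, image_size = c(48, 48), seed = 8)
  ds <- generate_dataset(cfg)
  sp <- split_samples(ds, train_frac = 0.8, seed = 4)
  expect_length(sp$train, 8); expect_length(sp$test, 2)
  ids <- function(xs) vapply(xs, function(s) s$meta$area_frac, 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- split_samples(ds, train_frac = 0.8, seed = 4)
  expect_identical(ids(sp2$train), ids(sp$train))
  expect_error(split_samples(ds[1:3]), "at least 5")
})
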