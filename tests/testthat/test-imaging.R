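test_that("extract_green selects and rescales the green plane", {
  rgb <- array(0, c(8, 8, 3))
  rgb[, , 2] <- 0.5
  expect_equal(extract_green(rgb), matrix(0.5, 8, 8))
  mono <- matrix(seq(0, 65535, length.out = 64), 8, 8)
  out <- extract_green(mono, intensity_range = c(0, 65535))
  expect_equal(max(out), 1)
  expect_equal(min(out), 0)
  expect_error(extract_green(array(0, c(4, 4, 2)), green_index = 3),
               "channel")
})

test_that("clahe is deterministic, bounded, and increases low-contrast spot separation", {
  expect_equal(clahe(matrix(0.5, 32, 32)), matrix(0.5, 32, 32))
  cfg <- image_sim_config(height = 128, width = 128,
                          n_spots_range = c(8, 8),
                          spot_amplitude_range = c(0.1, 0.12),
                          background_level = 0.05, gaussian_sd = 0.005)
  sim <- simulate_ev_image(cfg, seed = 21)
  ch <- sim$image
  out1 <- clahe(ch)
  out2 <- clahe(ch)
  expect_identical(out1, out2)
  expect_true(all(out1 >= 0 & out1 <= 1))
  fg <- sim$gt$true_mask == 1
  sep_before <- mean(ch[fg]) - mean(ch[!fg])
  sep_after <- mean(out1[fg]) - mean(out1[!fg])
  expect_gt(sep_after, sep_before)
  expect_error(clahe(matrix(0.2, 8, 8), clip_limit = 0), "clip_limit")
})

test_that("denoising respects its method contracts", {
  flat <- matrix(0.4, 16, 16)
  expect_equal(denoise_channel(flat, "median"), flat)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  out <- denoise_channel(imp, "median", param = 1)
  expect_equal(out[8, 8], 0)
  noisy <- matrix(runif(256), 16, 16)
  med <- denoise_channel(noisy, "median")
  # the median filter selects among (quantized) input values
  nearest <- vapply(as.numeric(med), function(v) min(abs(v - noisy)),
                    numeric(1))
  expect_lt(max(nearest), 2 / 65535)
  expect_equal(denoise_channel(noisy, "gaussian", param = 1e-6), noisy,
               tolerance = 1e-6)
  expect_error(denoise_channel(noisy, "boxcar"), "arg")
})

test_that("auto_mask recovers well-separated spots and rejects empty images", {
  cfg <- image_sim_config(n_spots_range = c(5, 5), gaussian_sd = 0)
  sim <- simulate_ev_image(cfg, seed = 12)
  m <- auto_mask(sim$image)
  expect_s3_class(m, "mask_image")
  expect_equal(m$object_count, 5)
  bg <- simulate_ev_image(image_sim_config(n_spots_range = c(0, 0)), seed = 1)
  expect_equal(auto_mask(bg$image)$object_count, 0)
  expect_equal(auto_mask(matrix(0.3, 32, 32))$object_count, 0)
})

test_that("merged spots stay covered even when unresolvable", {
  # two PSFs three pixels apart cannot be split by a global threshold
  ii <- 1:64
  s1 <- outer((ii - 30)^2, (ii - 32)^2, "+")
  s2 <- outer((ii - 33)^2, (ii - 32)^2, "+")
  ch <- 0.05 + 0.6 * exp(-s1 / (2 * 1.5^2)) + 0.6 * exp(-s2 / (2 * 1.5^2))
  ch <- pmin(ch, 1)
  m <- auto_mask(ch)
  expect_lte(m$object_count, 2)
  expect_equal(m$pixels[30, 32], 1L)
  expect_equal(m$pixels[33, 32], 1L)
})

test_that("component counting respects connectivity", {
  expect_equal(count_objects(matrix(0L, 8, 8)), 0)
  diagm <- matrix(0L, 4, 4)
  diagm[2, 2] <- 1L; diagm[3, 3] <- 1L
  expect_equal(count_objects(diagm, connectivity = 8), 1)
  expect_equal(count_objects(diagm, connectivity = 4), 2)
  sim <- simulate_ev_image(image_sim_config(n_spots_range = c(7, 7),
                                            gaussian_sd = 0), seed = 5)
  expect_equal(count_objects(sim$gt$true_mask), sim$gt$true_count)
  expect_error(count_objects(matrix(2, 3, 3)), "binary")
})

test_that("tiling partitions counts and resizes to the network input", {
  sim <- simulate_ev_image(image_sim_config(height = 512, width = 512,
                                            n_spots_range = c(30, 30)),
                           seed = 3)
  ts <- tile_image(sim$image, sim$gt$true_mask, tile_px = 128,
                   stride_px = 128)
  expect_length(ts, 16)
  expect_true(all(vapply(ts, function(t) all(dim(t$image) == c(128, 128)),
                         logical(1))))
  expect_equal(sum(vapply(ts, `[[`, integer(1), "count")),
               count_objects(sim$gt$true_mask))
  # a larger source tile is resampled down to 128
  ts2 <- tile_image(sim$image, sim$gt$true_mask, tile_px = 256,
                    stride_px = 256)
  expect_true(all(dim(ts2[[1]]$image) == c(128, 128)))
  expect_true(all(ts2[[1]]$mask %in% c(0L, 1L)))
  expect_error(tile_image(matrix(0, 64, 64), matrix(0L, 64, 64),
                          tile_px = 128), "tile larger")
})

test_that("augmentation multiplies tiles and preserves counts", {
  ts <- make_tiles(n_images = 2)
  aug <- augment_tiles(ts, n_aug = 10, seed = 3)
  expect_length(aug, 10 * length(ts))
  expect_equal(vapply(aug, `[[`, integer(1), "count"),
               rep(vapply(ts, `[[`, integer(1), "count"), each = 10))
  for (tl in aug[1:10]) {
    expect_equal(count_objects(tl$mask), count_objects(ts[[1]]$mask))
  }
  aug2 <- augment_tiles(ts, n_aug = 10, seed = 3)
  expect_identical(aug, aug2)
})

test_that("preprocess-and-mask is a pure function of image and config", {
  sim <- simulate_ev_image(image_sim_config(), seed = 31)
  pipeline <- function(img) {
    auto_mask(denoise_channel(clahe(extract_green(img))))
  }
  expect_identical(pipeline(sim$image), pipeline(sim$image))
})

test_that("images, masks and set files round-trip through disk formats", {
  tmp <- withr::local_tempdir()
  img <- matrix(runif(64 * 64), 64, 64)
  tif <- file.path(tmp, "x.tif")
  write_image(img, tif)
  back <- read_image(tif)
  expect_lt(max(abs(matrix(back, 64, 64) - img)), 1e-4)
  mk <- mask_image(matrix(rbinom(64, 1, 0.4), 8, 8))
  pngf <- file.path(tmp, "m.png")
  write_mask(mk, pngf)
  expect_equal(matrix(as.integer(read_image(pngf) > 0.5), 8, 8), mk$pixels)
  db <- list(pw1 = list(genes = c("A", "B"), mirnas = "m1",
                        metabolites = character(0)),
             pw2 = c("X", "Y", "Z"))
  gmt <- file.path(tmp, "sets.gmt")
  write_gmt(db, gmt)
  back_db <- read_gmt(gmt)
  expect_equal(back_db$pw1$genes, c("A", "B"))
  expect_equal(back_db$pw1$mirnas, "m1")
  expect_equal(back_db$pw2, c("X", "Y", "Z"))
})
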