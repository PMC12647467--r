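# Mask-consistent augmentation: identity behaviour, geometric invariants,
# determinism, pipeline counts and the background-reducing crops.

test_that("a degenerate configuration is the identity transform", {
  sc <- tiny_scenes(1)[[1]]
  a <- augment_pair(sc$image, sc$mask, identity_aug_config())
  expect_identical(a$mask, sc$mask)
  expect_equal(a$image, sc$image, tolerance = 1e-9)
})

test_that("hflip-only draws mirror the mask exactly and preserve class counts", {
  sc <- tiny_scenes(1, seed = 7)[[1]]
  cfg <- augmentation_config(hflip = TRUE, vflip = FALSE, scale = c(1, 1),
                             translate = 0, rotate = 0, brightness = 0,
                             hue = 0, saturation = 0, contrast = c(1, 1),
                             gaussian_noise = 0, gaussian_blur = 0, seed = 1L)
  # find a draw whose hflip coin lands TRUE
  flipped <- NULL
  for (d in 1:10) {
    a <- augment_pair(sc$image, sc$mask, cfg, draw_index = d)
    if (a$transform$hflip) { flipped <- a; break }
  }
  expect_false(is.null(flipped))
  W <- ncol(sc$mask)
  expect_identical(flipped$mask, sc$mask[, W:1])
  expect_identical(table(flipped$mask), table(sc$mask))
  # vflip analogue
  cfgv <- augmentation_config(hflip = FALSE, vflip = TRUE, scale = c(1, 1),
                              translate = 0, rotate = 0, brightness = 0,
                              hue = 0, saturation = 0, contrast = c(1, 1),
                              gaussian_noise = 0, gaussian_blur = 0, seed = 1L)
  for (d in 1:10) {
    a <- augment_pair(sc$image, sc$mask, cfgv, draw_index = d)
    if (a$transform$vflip) {
      expect_identical(a$mask, sc$mask[nrow(sc$mask):1, ])
      break
    }
  }
})

test_that("augmented masks keep labels in {0,1,2} and replaying the record reproduces them", {
  scenes <- tiny_scenes(3, seed = 31)
  cfg <- augmentation_config(seed = 5L)
  for (i in seq_along(scenes)) {
    for (d in 1:4) {
      a <- augment_pair(scenes[[i]]$image, scenes[[i]]$mask, cfg, d, i)
      expect_true(all(a$mask %in% 0:2))
      expect_identical(apply_transform_mask(scenes[[i]]$mask, a$transform),
                       a$mask)
      expect_true(all(a$image >= 0 & a$image <= 1))
    }
  }
})

test_that("augment_dataset yields exactly count-per-image outputs with provenance, deterministically", {
  scenes <- tiny_scenes(4, seed = 8)
  cfg <- augmentation_config(per_image_count = 3L, seed = 2L)
  out1 <- augment_dataset(scenes, cfg)
  expect_length(out1, 12L)
  expect_identical(vapply(out1, `[[`, character(1), "source_id"),
                   rep(vapply(scenes, `[[`, character(1), "id"), each = 3L))
  expect_identical(vapply(out1, `[[`, integer(1), "draw_index"),
                   rep(1:3, 4))
  out2 <- augment_dataset(scenes, cfg)
  expect_identical(out1, out2)
  # unit case
  expect_length(augment_dataset(scenes[1], augmentation_config(
    per_image_count = 1L)), 1L)
  expect_error(augment_dataset(list(), cfg), "empty")
})

test_that("crop augmentation multiplies counts and reduces mean background fraction", {
  scenes <- tiny_scenes(20, seed = 77)
  cfg <- crop_config(crops_per_image = 5L, crop_size = c(48L, 48L), seed = 3L)
  crops <- crop_augment_dataset(scenes, cfg)
  expect_length(crops, 100L)
  bg_in <- mean(vapply(scenes, function(s) mean(s$mask == 0L), numeric(1)))
  bg_out <- mean(vapply(crops, function(s) mean(s$mask == 0L), numeric(1)))
  expect_lt(bg_out, bg_in)
  expect_true(all(vapply(crops, function(c) all(dim(c$mask) == c(48, 48)),
                         logical(1))))
  # determinism and the stem-weighted rule
  crops2 <- crop_augment_dataset(scenes, cfg)
  expect_identical(crops, crops2)
  cfgs <- crop_config(crops_per_image = 2L, crop_size = c(48L, 48L),
                      selection_rule = "stem_fraction_weighted", seed = 3L)
  cw <- crop_augment_dataset(scenes[1:5], cfgs)
  expect_length(cw, 10L)
  stem_frac <- mean(vapply(cw, function(s) mean(s$mask == 1L), numeric(1)))
  expect_gt(stem_frac, mean(vapply(scenes[1:5], function(s)
    mean(s$mask == 1L), numeric(1))))
})

test_that("an all-background image degrades to uniform random crops without error", {
  blank <- list(id = "blank",
                image = array(0.05, dim = c(96, 160, 3)),
                mask = matrix(0L, 96, 160))
  crops <- crop_augment_dataset(list(blank), crop_config(
    crops_per_image = 3L, crop_size = c(32L, 32L), seed = 1L))
  expect_length(crops, 3L)
  expect_true(all(vapply(crops, function(c) all(c$mask == 0L), logical(1))))
  expect_error(crop_augment_dataset(list(blank), crop_config(
    crop_size = c(200L, 200L))), "exceeds")
})

test_that("augmented datasets write to disk with a provenance manifest", {
  scenes <- tiny_scenes(2, seed = 55)
  aug <- augment_dataset(scenes, augmentation_config(per_image_count = 2L,
                                                     seed = 4L))
  outd <- tempfile()
  mp <- write_augmented_dataset(aug, outd)
  expect_true(file.exists(mp))
  man <- jsonlite::fromJSON(mp, simplifyDataFrame = FALSE)
  expect_length(man, 4L)
  f <- file.path(outd, paste0(aug[[1]]$id, "_mask.png"))
  expect_identical(read_mask(f), aug[[1]]$mask)
})
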