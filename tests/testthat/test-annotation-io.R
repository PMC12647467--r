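# Polygon rasterization, mask file I/O, resizing and dataset splits.

test_that("rasterization: empty list, closed-form rectangle, overlap order, degenerate polygon", {
  expect_identical(rasterize_annotations(list(), 16L, 16L), matrix(0L, 16, 16))
  # axis-aligned rectangle covering pixel centers x in 10..19, y in 5..14
  rect <- polygon_annotation("leaf",
    rbind(c(10, 5), c(20, 5), c(20, 15), c(10, 15)), c(32L, 32L))
  m <- rasterize_annotations(list(rect), 32L, 32L)
  expect_identical(sum(m == 2L), 100L)
  expect_identical(sort(unique(as.vector(m))), c(0L, 2L))
  expect_true(all(m[6:15, 11:20] == 2L))
  # later polygons overwrite earlier ones (file order wins)
  stem <- polygon_annotation("branch",
    rbind(c(12, 7), c(16, 7), c(16, 11), c(12, 11)), c(32L, 32L))
  m2 <- rasterize_annotations(list(rect, stem), 32L, 32L)
  expect_identical(sum(m2 == 1L), 16L)
  expect_identical(sum(m2 != 0L), 100L)
  # degenerate and unknown labels
  expect_warning(rasterize_annotations(list(polygon_annotation(
    "leaf", rbind(c(1, 1), c(2, 2)), c(8L, 8L))), 8L, 8L), "degenerate")
  expect_error(rasterize_annotations(list(polygon_annotation(
    "flower", rbind(c(1, 1), c(4, 1), c(2, 4)), c(8L, 8L))), 8L, 8L),
    "unknown")
})

test_that("rasterization equals the even-odd point-in-polygon oracle on random simple polygons", {
  set.seed(201)
  for (i in 1:20) {
    v <- random_simple_polygon(64L, 64L, sample(5:10, 1))
    got <- rasterize_annotations(
      list(polygon_annotation("branch", v, c(64L, 64L))), 64L, 64L)
    expect_identical(got, rasterize_oracle(v, 64L, 64L, 1L))
  }
})

test_that("rasterization is invariant under cyclic vertex rotation", {
  set.seed(202)
  v <- random_simple_polygon(48L, 48L, 7L)
  m0 <- rasterize_annotations(
    list(polygon_annotation("leaf", v, c(48L, 48L))), 48L, 48L)
  for (k in c(2, 5)) {
    vr <- v[c(k:nrow(v), 1:(k - 1)), ]
    mr <- rasterize_annotations(
      list(polygon_annotation("leaf", vr, c(48L, 48L))), 48L, 48L)
    expect_identical(mr, m0)
  }
})

test_that("mask PNG write/read round-trips exactly and previews are writable", {
  set.seed(203)
  mask <- matrix(sample(0:2, 24 * 30, TRUE), 24)
  path <- tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(read_mask(path), mask)
  prev <- tempfile(fileext = ".png")
  write_mask_preview(mask, prev)
  expect_true(file.exists(prev))
  img <- array(runif(24 * 30 * 3), dim = c(24, 30, 3))
  ip <- tempfile(fileext = ".png")
  write_image(img, ip)
  expect_lt(max(abs(read_image(ip) - img)), 1 / 255)
})

test_that("labelme JSON files parse and convert to masks", {
  j <- list(imageHeight = 24L, imageWidth = 32L,
            shapes = list(
              list(label = "branch",
                   points = list(c(2, 2), c(12, 2), c(12, 6), c(2, 6))),
              list(label = "leaf",
                   points = list(c(5, 8), c(15, 8), c(15, 16), c(5, 16)))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  lj <- read_labelme(path)
  expect_identical(lj$image_size, c(24L, 32L))
  expect_length(lj$annotations, 2L)
  mask <- rasterize_annotations(lj$annotations, 24L, 32L)
  expect_identical(sum(mask == 1L), 40L)   # 10 x 4 rectangle
  expect_identical(sum(mask == 2L), 80L)   # 10 x 8 rectangle
  # directory conversion
  outd <- tempfile()
  dir.create(dirname(path), showWarnings = FALSE)
  jd <- tempfile(); dir.create(jd)
  file.copy(path, file.path(jd, "a.json"))
  convert_annotations(jd, outd)
  expect_identical(read_mask(file.path(outd, "a.png")), mask)
})

test_that("resize_sample: identity, label closure, and exact 2x nearest mapping", {
  set.seed(204)
  img <- array(runif(16 * 20 * 3), dim = c(16, 20, 3))
  mask <- matrix(sample(0:2, 16 * 20, TRUE), 16)
  same <- resize_sample(img, mask, c(16L, 20L))
  expect_equal(same$image, img, tolerance = 1e-6)
  expect_identical(same$mask, mask)
  down <- resize_sample(img, mask, c(8L, 12L))
  expect_true(all(unique(as.vector(down$mask)) %in% unique(as.vector(mask))))
  # single-pixel island upscales to an exact 2x2 block
  m1 <- matrix(0L, 8, 8); m1[3, 5] <- 1L
  up <- resize_sample(NULL, m1, c(16L, 16L))$mask
  expect_identical(sum(up == 1L), 4L)
  expect_true(all(up[5:6, 9:10] == 1L))
  expect_error(resize_sample(img, mask, c(0L, 8L)), "positive")
})

test_that("split_dataset partitions a 300-image corpus into 175/75/50 deterministically", {
  ids <- sprintf("im%03d", 1:300)
  sp <- split_dataset(ids, c(0.7, 0.3), test_count = 50L, seed = 9L)
  expect_length(sp$train_ids, 175L)
  expect_length(sp$val_ids, 75L)
  expect_length(sp$test_ids, 50L)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  sp2 <- split_dataset(ids, c(0.7, 0.3), test_count = 50L, seed = 9L)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(ids, c(0.7, 0.3), test_count = 50L, seed = 10L)
  expect_false(identical(sp$test_ids, sp3$test_ids))
  expect_error(split_dataset(ids[1:10], test_count = 10L), "more ids")
})
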