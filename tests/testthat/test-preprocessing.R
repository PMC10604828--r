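test_that("bicubic resize meets its shape and preservation contracts", {
  img <- gradient_image(16, 16)
  big <- array(runif(256 * 256 * 3, 0, 255), dim = c(256, 256, 3))
  out <- resize_image(big, c(128, 128))
  expect_equal(dim(out), c(128, 128, 3))
  # constants are preserved exactly
  expect_equal(resize_image(const_image(10, 14, 37), c(128, 128)),
               const_image(128, 128, 37))
  # identity resize reproduces the input
  expect_equal(resize_image(img, c(16, 16)), img, tolerance = 1e-10)
  expect_error(resize_image(matrix(1, 4, 4)), "format error")
})

test_that("the four scaling transforms match their definitions", {
  img <- gradient_image(8, 8)
  img[1, 1, 1] <- 0; img[8, 8, 3] <- 255
  mm <- scale_image(img, "minmax")
  expect_equal(range(mm), c(0, 1))
  st <- scale_image(img, "standard")
  expect_equal(mean(st), 0, tolerance = 1e-6)
  expect_equal(sd(st), 1, tolerance = 1e-6)
  expect_equal(scale_image(const_image(4, 4, 200), "normalize"),
               const_image(4, 4, 1))
  nm <- scale_image(img, "normalize")
  expect_equal(max(nm), 1)
  ma <- scale_image(img, "maxabs")
  expect_true(all(ma >= -1 & ma <= 1))
  expect_warning(scale_image(const_image(4, 4, 9), "minmax"), "degenerate")
  expect_warning(scale_image(const_image(4, 4, 9), "standard"), "degenerate")
})

test_that("scaling outputs stay in their documented ranges under fuzz", {
  set.seed(21)
  for (i in 1:20) {
    img <- array(runif(4 * 4 * 3, 0, 255), dim = c(4, 4, 3))
    expect_true(all(scale_image(img, "minmax") >= 0 &
                      scale_image(img, "minmax") <= 1))
    m <- scale_image(img, "maxabs")
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("augmentation is identity at zero magnitudes and flips are involutions", {
  img <- gradient_image(12, 12)
  id_cfg <- augmentation_config(rotation_deg = 0, width_shift = 0,
                                height_shift = 0, shear = 0, zoom = 0,
                                brightness = c(1, 1),
                                horizontal_flip = FALSE,
                                vertical_flip = FALSE)
  expect_identical(augment_image(img, id_cfg), img)
  expect_identical(flip_image(flip_image(img, "horizontal"), "horizontal"), img)
  expect_identical(flip_image(flip_image(img, "vertical"), "vertical"), img)
  expect_false(identical(flip_image(img, "horizontal"), img))
})

test_that("rotation moves a bright pixel within its predicted annulus", {
  img <- const_image(33, 33, 0)
  img[17, 27, ] <- 255  # radius 10 from the center, to the right
  cfg <- augmentation_config(rotation_deg = 30, width_shift = 0,
                             height_shift = 0, shear = 0, zoom = 0,
                             brightness = c(1, 1), horizontal_flip = FALSE,
                             vertical_flip = FALSE)
  set.seed(8)
  for (i in 1:5) {
    out <- augment_image(img, cfg)
    peak <- which(out[, , 1] == max(out[, , 1]), arr.ind = TRUE)[1, ]
    radius <- sqrt((peak[1] - 17)^2 + (peak[2] - 17)^2)
    expect_lt(abs(radius - 10), 2)  # bilinear spread tolerance
  }
})

test_that("augmentation preserves label, shape and intensity range", {
  ds <- make_synthetic_imageset(c(2, 2), size = c(16, 16), seed = 5)
  cfg <- default_balancing_config()
  set.seed(3)
  for (i in seq_along(ds$images)) {
    out <- augment_image(ds$images[[i]], cfg)
    expect_equal(dim(out), dim(ds$images[[i]]))
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("augmentation balancing equalizes class counts without removals", {
  ds <- tiny_dataset(c(1, 3), h = 4, w = 4)
  bal <- balance_by_augmentation(ds, seed = 2)
  expect_equal(unname(table(bal$labels)[c("normal", "lesion")]),
               c(3L, 3L), ignore_attr = TRUE)
  # originals retained: the single normal image is still present
  expect_true(any(vapply(bal$images[bal$labels == "normal"],
                         function(im) identical(im, ds$images[[1]]),
                         logical(1))))
  expect_equal(sum(grepl("#aug", bal$provenance)), 2)
  # already balanced input is unchanged
  even <- tiny_dataset(c(3, 3))
  expect_identical(balance_by_augmentation(even, seed = 2)$images, even$images)
  empty <- image_dataset(list(), character())
  expect_error(balance_by_augmentation(empty, seed = 1), "balance error")
})

test_that("nested partitioning yields the documented proportions and a true partition", {
  ds <- tiny_dataset(c(120, 80), h = 1, w = 1)
  sp <- partition_dataset(ds, seed = 6)
  expect_s3_class(sp, "split_dataset")
  expect_equal(length(sp$test), 30)          # 15% of 200
  expect_equal(length(sp$validation), 26)    # 15% of the remaining 170
  expect_equal(length(sp$train), 144)
  # partition law: union equals input, pairwise disjoint (record ids are
  # the distinct constant intensities)
  ids <- function(d) vapply(d$images, function(im) im[1, 1, 1], numeric(1))
  all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
  expect_setequal(all_ids, ids(ds))
  expect_equal(anyDuplicated(all_ids), 0)
  # determinism
  sp2 <- partition_dataset(ds, seed = 6)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(partition_dataset(tiny_dataset(c(1, 1)), seed = 1),
               "partition error")
})

test_that("stratified partitioning splits each class with the same ratios", {
  ds <- tiny_dataset(c(100, 100), h = 1, w = 1)
  sp <- partition_dataset(ds, seed = 4, stratify = TRUE)
  expect_equal(unname(table(sp$test$labels)), c(15L, 15L), ignore_attr = TRUE)
})

test_that("imageset round-trips through the directory-per-class PNG layout", {
  ds <- make_synthetic_imageset(c(3, 2), size = c(16, 16), seed = 9)
  dir <- withr::local_tempdir()
  write_imageset(ds, dir)
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                  c("normal", "lesion"))
  back <- read_imageset(dir)
  expect_equal(length(back), 5)
  expect_equal(sort(table(back$labels), decreasing = TRUE),
               sort(table(ds$labels), decreasing = TRUE))
  # 8-bit fidelity through the PNG writer/reader
  orig <- ds$images[[which(ds$labels == "lesion")[1]]]
  candidates <- back$images[back$labels == "lesion"]
  expect_true(any(vapply(candidates, function(im)
    max(abs(im - orig)) < 0.51, logical(1))))
  manifest <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(partition_dataset(back, seed = 1), manifest)
  df <- read.csv(manifest)
  expect_equal(nrow(df), 5)
  expect_setequal(unique(df$split), c("train", "validation", "test"))
})
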