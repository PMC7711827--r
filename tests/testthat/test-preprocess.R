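test_that("grayscale conversion uses ITU-R 601 weights and passes 1-channel through", {
  rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 1
  expect_equal(to_grayscale(rgb)[1, 1], 0.299)
  achro <- array(0.4, c(2, 2, 3))
  expect_equal(to_grayscale(achro), matrix(0.4, 2, 2))
  m <- matrix(runif(6), 2, 3)
  expect_identical(to_grayscale(m), m)
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "channel")
})

test_that("resize_pad geometry: whole-body 1024x256 maps to a 224x56 content region", {
  img <- matrix(1, 1024, 256)
  out <- resize_pad(img, 224)
  expect_equal(dim(out), c(224L, 224L))
  expect_equal(attr(out, "content_height"), 224L)
  expect_equal(attr(out, "content_width"), 56L)     # 256 * 224/1024
  # 84 zero columns on each side
  expect_true(all(out[, 1:84] == 0))
  expect_true(all(out[, 141:224] == 0))
  expect_true(all(out[, 85:140] > 0))
  # transposed input follows the same rule on rows
  outT <- resize_pad(t(img), 224)
  expect_equal(attr(outT, "content_height"), 56L)
  expect_true(all(outT[1:84, ] == 0) && all(outT[169:224, ] == 0))
  # square input of the target size is untouched
  sq <- matrix(runif(224^2), 224, 224)
  expect_equal(resize_pad(sq, 224), sq, ignore_attr = TRUE)
  expect_error(resize_pad(matrix(numeric(0), 0, 0), 224), "zero-sized")
})

test_that("resize_pad preserves the aspect ratio within quantization", {
  for (hw in list(c(512, 128), c(300, 200), c(64, 256))) {
    out <- resize_pad(matrix(1, hw[1], hw[2]), 96)
    got <- attr(out, "content_height") / attr(out, "content_width")
    expect_equal(got, hw[1] / hw[2], tolerance = 2 / min(attr(out, "content_height"),
                                                         attr(out, "content_width")))
  }
})

test_that("normalization divides by the bit-depth maximum, not the image maximum", {
  img <- matrix(c(0, 32768, 65535, 100), 2, 2)
  out <- normalize_pixels(img, 16L)
  expect_equal(out[1, 2], 1)                     # 65535 -> 1
  expect_equal(out[2, 1], 32768 / 65535)         # 0.50000762...
  expect_equal(normalize_pixels(matrix(0, 3, 3)), matrix(0, 3, 3))
  # idempotent once on the unit scale
  expect_identical(normalize_pixels(out, 0L), out)
  expect_error(normalize_pixels(matrix(-1, 1, 1)), "negative")
})

test_that("augmentation preserves label and shape; identity transform is exact", {
  cfg <- preprocess_config(rotation_max_deg = 0, rescale_range = c(1, 1))
  img <- matrix(runif(32 * 32), 32, 32)
  set.seed(1)
  out <- augment_image(img, "malignant", cfg)
  expect_identical(out$label, "malignant")
  expect_equal(dim(out$image), dim(img))
  expect_equal(out$image, img, tolerance = 1e-12)   # zero rotation, unit zoom
  cfg2 <- preprocess_config(rotation_max_deg = 15, rescale_range = c(0.8, 1.2))
  for (i in 1:5) {
    out2 <- augment_image(img, "normal", cfg2)
    expect_identical(out2$label, "normal")
    expect_equal(dim(out2$image), dim(img))
  }
})

test_that("preprocess_dataset emits the (n, size, size, channels) tensor and labels", {
  ds <- generate_dataset(small_phantom(seed = 8))
  data <- preprocess_dataset(ds, preprocess_config(target_size = 24))
  expect_equal(dim(data$x), c(12, 24, 24, 3))
  expect_true(all(data$x >= 0 & data$x <= 1))
  expect_setequal(unique(data$y), 0:2)
  expect_identical(data$y, class_index(ds$manifest$label))
  # channel replication: all three planes identical
  expect_identical(data$x[, , , 1], data$x[, , , 2])
  expect_error(class_index("equivocal"), "unknown class")
})
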