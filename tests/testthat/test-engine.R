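# The numeric engine is the package's own execution backend; these tests pin
# its correctness independently of any architecture-level claim.

test_that("backpropagation matches central finite differences in double precision", {
  spec <- tiny_spec()
  arch <- scintnet:::arch_list(spec)
  w <- scintnet:::cpp_net_init(arch, 7L)
  st <- scintnet:::cpp_net_init_state(arch)
  set.seed(1)
  x <- array(runif(4 * 16 * 16), c(4, 16, 16, 1))
  y <- c(0L, 1L, 2L, 1L)
  g <- scintnet:::cpp_net_loss_grad(arch, w, st, x, y)
  expect_true(is.finite(g$loss))
  h <- 1e-5
  idx <- sort(sample(seq_along(w), 60))
  for (i in idx) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    fd <- (scintnet:::cpp_net_loss_grad(arch, wp, st, x, y)$loss -
           scintnet:::cpp_net_loss_grad(arch, wm, st, x, y)$loss) / (2 * h)
    expect_lt(abs(fd - g$grad[i]) / max(1e-6, abs(fd) + abs(g$grad[i])), 1e-5)
  }
})

test_that("weight initialization is seeded and sized by the layout", {
  spec <- tiny_spec()
  arch <- scintnet:::arch_list(spec)
  expect_identical(scintnet:::cpp_net_nparams(arch), as.double(spec$total_params))
  w1 <- scintnet:::cpp_net_init(arch, 11L)
  w2 <- scintnet:::cpp_net_init(arch, 11L)
  w3 <- scintnet:::cpp_net_init(arch, 12L)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  # fresh batch-norm state: running means 0, running variances 1
  st <- scintnet:::cpp_net_init_state(arch)
  expect_identical(sort(unique(st)), c(0, 1))
  expect_identical(length(st), as.integer(scintnet:::cpp_net_nstate(arch)))
})

test_that("forward pass dimensions are input-size agnostic (fully convolutional)", {
  for (size in c(16L, 32L)) {
    spec <- tiny_spec(size)
    m <- instantiate_model(spec, 2)
    x <- array(runif(2 * size * size), c(2, size, size, 1))
    p <- predict(m, x)
    expect_equal(dim(p), c(2L, 3L))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  }
  # identical weight budget at both sizes
  expect_identical(tiny_spec(16L)$total_params, tiny_spec(32L)$total_params)
})

test_that("batch-norm calibration reconciles training and inference statistics", {
  ds <- generate_dataset(phantom_config(image_height = 128L, image_width = 32L,
    class_counts = c(malignant = 15L, degenerative = 15L, normal = 15L), seed = 13))
  data <- preprocess_dataset(ds, preprocess_config(target_size = 16, channels = 1))
  spec <- tiny_spec(16L, 1L)
  fit <- train_fold(instantiate_model(spec, 1), data$x, data$y,
                    train_config(epochs = 4, seed = 1, augment = TRUE,
                                 rotation_max_deg = 5, rescale_range = c(0.95, 1.05)))
  # calibrated state differs from the raw momentum-tracked state and yields
  # sane probabilities on clean data
  p <- predict(fit, data$x)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 45), tolerance = 1e-5)
})

test_that("geometric transforms are exact in their identity limits", {
  img <- matrix(runif(20 * 12), 20, 12)
  expect_equal(scintnet:::cpp_rotate_zoom(img, 0, 1), img, tolerance = 1e-12)
  expect_equal(scintnet:::cpp_resize_bilinear(img, 20L, 12L), img)
  # 2x downscale of a constant image stays constant
  cimg <- matrix(5, 32, 32)
  expect_equal(scintnet:::cpp_resize_bilinear(cimg, 16L, 16L), matrix(5, 16, 16))
  # rotation keeps mass approximately (interior content, small angle)
  blob <- matrix(0, 21, 21); blob[9:13, 9:13] <- 1
  rot <- scintnet:::cpp_rotate_zoom(blob, 7, 1)
  expect_equal(sum(rot), sum(blob), tolerance = 0.05)
})
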