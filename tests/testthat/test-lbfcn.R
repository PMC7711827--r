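test_that("separable convolution parameter formula", {
  expect_identical(separable_conv_params(3, 8, 16), 200L)          # 72 + 128
  C <- 13L
  expect_identical(separable_conv_params(1, C, C), C + C * C)      # k = 1 limit
  expect_error(separable_conv_params(0, 8, 16), "positive")
  # lightness of the factorization: standard / separable ~ 7.9 at k=3, 64->64
  std <- standard_conv_params(3, 64, 64)
  sep <- separable_conv_params(3, 64, 64)
  expect_identical(std, 36864L)
  expect_identical(sep, 4672L)
  expect_equal(std / sep, 7.89, tolerance = 0.001)
})

test_that("multi-scale blocks assemble with concat arithmetic and shape repair", {
  blk <- multiscale_block_spec(16, residual = FALSE)
  tab <- build_block(blk, 8)
  expect_identical(tab$out_channels[tab$kind == "concat"], 48L)    # 3 x 16
  expect_false(any(tab$kind == "pointwise_conv"))
  # residual with channel mismatch auto-inserts the projection
  blkr <- multiscale_block_spec(16, residual = TRUE)
  tabr <- build_block(blkr, 8)
  expect_identical(sum(tabr$kind == "pointwise_conv"), 1L)
  expect_equal(tabr$params[tabr$kind == "pointwise_conv"], 8L * 48L)
  # block parameter total equals the brute-force sum over its layer rows
  expect_equal(sum(tabr$params),
               sum(vapply(seq_len(nrow(tabr)), function(i) as.numeric(tabr$params[i]), numeric(1))))
  expect_error(multiscale_block_spec(16, kernels = 3, dilations = 1), ">= 2 branches")
})

test_that("frozen LB-FCN light sits in the parameter budget with 3 residuals", {
  spec <- build_lbfcn_light()
  expect_gte(spec$total_params, 300000L)
  expect_lte(spec$total_params, 322886L)
  expect_identical(format_millions(spec$total_params), "0.3")
  expect_identical(format_millions(spec$flops), "0.6")
  expect_identical(spec$residual_count, 3L)
  expect_identical(sum(spec$layers$kind == "add"), 3L)
  # fully convolutional: no dense layer other than the softmax head
  expect_identical(sum(spec$layers$kind == "softmax_dense"), 1L)
  expect_identical(spec$total_params, sum(spec$layers$params))
})

test_that("parameter count is invariant to spatial size, sensitive only to channels", {
  p224 <- build_lbfcn_light(input_size = 224L)$total_params
  p112 <- build_lbfcn_light(input_size = 112L)$total_params
  expect_identical(p224, p112)
  s3 <- build_lbfcn_light(channels = 3L)
  s1 <- build_lbfcn_light(channels = 1L)
  d3 <- s3$layers; d1 <- s1$layers
  diff_rows <- which(d3$params != d1$params)
  # only first-block layers may differ between channel modes
  expect_true(all(grepl("^block1", d3$name[diff_rows])))
  # and the difference is exactly the extra depthwise + pointwise input terms
  expect_identical(s3$total_params - s1$total_params,
                   sum(d3$params[diff_rows]) - sum(d1$params[diff_rows]))
})

test_that("instantiated models agree with the spec count and emit probabilities", {
  spec <- tiny_spec()
  model <- instantiate_model(spec, seed = 4)
  expect_identical(model_param_count(model), spec$total_params)
  x <- array(runif(3 * 16 * 16), c(3, 16, 16, 1))
  p <- predict(model, x)
  expect_equal(dim(p), c(3L, 3L))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # backend count equals spec count for the full-size network too
  full <- build_lbfcn_light()
  expect_identical(instantiate_model(full)$spec$total_params, full$total_params)
})

test_that("network spec serializes to JSON and CSV", {
  spec <- tiny_spec()
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  network_spec_json(spec, jf)
  js <- jsonlite::read_json(jf)
  expect_identical(js$total_params, spec$total_params)
  expect_identical(js$residual_count, 3L)
  write_layer_table(spec, cf)
  tab <- read.csv(cf)
  expect_identical(sum(tab$params), spec$total_params)
  unlink(c(jf, cf))
})
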