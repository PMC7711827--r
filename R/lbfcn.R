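#' Parameter count of a depthwise separable convolution
#'
#' A separable convolution holds one `k x k` spatial filter per input
#' channel (depthwise stage) plus a `1 x 1` pointwise convolution mixing
#' `in_channels` into `out_channels`: `k^2 * in + in * out` weights, with
#' optional bias and batch-norm terms under the documented convention
#' (convolutions in this package carry no bias — a batch normalization with
#' two trainable parameters per output channel follows instead).
#'
#' @param k Spatial kernel size (`k >= 1`).
#' @param in_channels,out_channels Channel counts (`>= 1`).
#' @param bias Add `out_channels` bias terms.
#' @param norm Add `2 * out_channels` batch-norm scale/shift terms.
#' @return Integer parameter count.
#' @export
separable_conv_params <- function(k, in_channels, out_channels,
                                  bias = FALSE, norm = FALSE) {
  if (k < 1 || in_channels < 1 || out_channels < 1)
    stop("kernel size and channel counts must be positive", call. = FALSE)
  n <- k^2 * in_channels + in_channels * out_channels
  if (bias) n <- n + out_channels
  if (norm) n <- n + 2 * out_channels
  as.integer(n)
}

#' Parameter count of a standard convolution
#'
#' `k^2 * in * out` weights (plus optional bias/norm); the reference point
#' for the separable factorization's savings.
#'
#' @inheritParams separable_conv_params
#' @export
standard_conv_params <- function(k, in_channels, out_channels,
                                 bias = FALSE, norm = FALSE) {
  if (k < 1 || in_channels < 1 || out_channels < 1)
    stop("kernel size and channel counts must be positive", call. = FALSE)
  n <- k^2 * in_channels * out_channels
  if (bias) n <- n + out_channels
  if (norm) n <- n + 2 * out_channels
  as.integer(n)
}

#' Multi-scale block specification
#'
#' One building block of the network: parallel separable-convolution
#' branches with different receptive fields on a shared input, channel
#' concatenation, an optional look-behind residual connection from the
#' block input (via a pointwise projection when channel counts differ), and
#' 2x2 max-pool downsampling.
#'
#' @param filters Filters per branch.
#' @param kernels,dilations Parallel branch definitions (default three
#'   branches: 3x3 dilation 1, 3x3 dilation 2, 5x5 dilation 1).
#' @param residual Attach the look-behind residual connection.
#' @return An object of class `multiscale_block_spec`.
#' @export
multiscale_block_spec <- function(filters, kernels = c(3, 3, 5),
                                  dilations = c(1, 2, 1), residual = TRUE) {
  if (length(kernels) < 2) stop("a multi-scale block needs >= 2 branches", call. = FALSE)
  if (length(kernels) != length(dilations))
    stop("kernels and dilations must have equal length", call. = FALSE)
  structure(list(filters = as.integer(filters), kernels = as.integer(kernels),
                 dilations = as.integer(dilations), residual = isTRUE(residual)),
            class = "multiscale_block_spec")
}

#' Layer table of one multi-scale block
#'
#' Expands a block specification into its constituent layers with exact
#' per-layer trainable parameter counts.
#'
#' @param spec A [multiscale_block_spec()].
#' @param in_channels Channels entering the block.
#' @param name Block name used in the layer table.
#' @return A data frame of layers (kind, kernel, dilation, in/out channels,
#'   params).
#' @export
build_block <- function(spec, in_channels, name = "block") {
  rows <- list()
  nb <- length(spec$kernels)
  merged <- nb * spec$filters
  for (j in seq_len(nb)) {
    k <- spec$kernels[j]; d <- spec$dilations[j]
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("%s_branch%d_sepconv", name, j), kind = "separable_conv",
      kernel = k, dilation = d, in_channels = in_channels, out_channels = spec$filters,
      params = separable_conv_params(k, in_channels, spec$filters))
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("%s_branch%d_bn", name, j), kind = "batch_norm",
      kernel = NA, dilation = NA, in_channels = spec$filters, out_channels = spec$filters,
      params = 2L * spec$filters)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = sprintf("%s_concat", name), kind = "concat", kernel = NA, dilation = NA,
    in_channels = in_channels, out_channels = merged, params = 0L)
  if (spec$residual) {
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("%s_residual_proj", name), kind = "pointwise_conv",
      kernel = 1, dilation = 1, in_channels = in_channels, out_channels = merged,
      params = as.integer(in_channels * merged))
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("%s_residual_bn", name), kind = "batch_norm",
      kernel = NA, dilation = NA, in_channels = merged, out_channels = merged,
      params = 2L * merged)
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("%s_residual_add", name), kind = "add", kernel = NA, dilation = NA,
      in_channels = merged, out_channels = merged, params = 0L)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = sprintf("%s_pool", name), kind = "pool", kernel = 2, dilation = NA,
    in_channels = merged, out_channels = merged, params = 0L)
  do.call(rbind, rows)
}

#' Build the LB-FCN light network specification
#'
#' The frozen default configuration of the lightweight look-behind fully
#' convolutional network: four multi-scale blocks (branch kernels 3x3
#' dilation 1, 3x3 dilation 2, 5x5 dilation 1; 16/40/88/130 filters per
#' branch), look-behind residual connections on blocks 2-4 (the first block
#' carries none, giving the stated 4-block/3-residual layout), depthwise
#' separable convolutions throughout, and a global-average-pooling 3-class
#' softmax head — the only non-convolutional trainable layer.  The default
#' lands at 304,014 trainable parameters, inside the 300,000-322,886 budget
#' window that floor-truncates to 0.3 x 10^6 while staying at least 10x
#' lighter than MobileNet.
#'
#' @param channels Input channel count, 1 or 3 (default 3, grayscale
#'   replicated).
#' @param input_size Square spatial input in px (default 224).  Parameter
#'   counts are invariant to this: the network is fully convolutional.
#' @param filters Per-branch filter counts of the four blocks.
#' @param n_classes Output classes (default 3).
#' @return An object of class `network_spec` with the per-layer table,
#'   `total_params` and the FLOP estimate.
#' @export
build_lbfcn_light <- function(channels = 3L, input_size = 224L,
                              filters = c(16L, 40L, 88L, 130L),
                              n_classes = 3L) {
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3", call. = FALSE)
  if (length(filters) != 4) stop("LB-FCN light has exactly four blocks", call. = FALSE)
  blocks <- lapply(seq_along(filters), function(b)
    multiscale_block_spec(filters[b], residual = b > 1))
  tabs <- list()
  cin <- channels
  for (b in seq_along(blocks)) {
    tabs[[b]] <- build_block(blocks[[b]], cin, sprintf("block%d", b))
    cin <- length(blocks[[b]]$kernels) * blocks[[b]]$filters
  }
  head_tab <- rbind(
    data.frame(name = "gap", kind = "global_average_pool", kernel = NA, dilation = NA,
               in_channels = cin, out_channels = cin, params = 0L),
    data.frame(name = "softmax_dense", kind = "softmax_dense", kernel = NA, dilation = NA,
               in_channels = cin, out_channels = n_classes,
               params = cin * n_classes + n_classes))
  layers <- do.call(rbind, c(tabs, list(head_tab)))
  rownames(layers) <- NULL
  total <- sum(layers$params)
  structure(list(input_shape = c(input_size, input_size, channels),
                 blocks = blocks, layers = layers,
                 residual_count = sum(vapply(blocks, function(b) b$residual, logical(1))),
                 n_classes = as.integer(n_classes),
                 total_params = as.integer(total),
                 flops = flops_estimate(total)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> LB-FCN light family: input %s, %d blocks, %d residual connections\n",
              paste(x$input_shape, collapse = "x"), length(x$blocks), x$residual_count))
  cat(sprintf("  trainable parameters: %s (%.1f x 10^6 truncated: %s)\n",
              format(x$total_params, big.mark = ","), x$total_params / 1e6,
              format_millions(x$total_params)))
  cat(sprintf("  FLOPs per inference (2 per parameter): %s\n",
              format(x$flops, big.mark = ",")))
  invisible(x)
}

#' @export
summary.network_spec <- function(object, ...) {
  print(object)
  tab <- object$layers[object$layers$params > 0, c("name", "kind", "in_channels", "out_channels", "params")]
  print(tab, row.names = FALSE)
  invisible(object$layers)
}

# Engine-facing architecture description (must mirror the C++ layout).
arch_list <- function(spec) {
  list(channels = spec$input_shape[3], input_size = spec$input_shape[1],
       n_classes = spec$n_classes,
       blocks = lapply(spec$blocks, function(b)
         list(kernels = b$kernels, dilations = b$dilations,
              filters = b$filters, residual = as.integer(b$residual))))
}

#' Instantiate an executable model from a network specification
#'
#' Allocates and initializes the weights of the package's numeric engine for
#' the given specification.  The engine's allocated weight-vector length is
#' an independent count of the trainable parameters and is required to equal
#' `spec$total_params` exactly.
#'
#' @param spec A [build_lbfcn_light()] specification.
#' @param seed Initialization seed.
#' @return An object of class `lbfcn_model`.
#' @export
instantiate_model <- function(spec, seed = 1L) {
  arch <- arch_list(spec)
  n_backend <- cpp_net_nparams(arch)
  if (n_backend != spec$total_params)
    stop(sprintf("backend parameter count (%d) disagrees with the specification (%d)",
                 n_backend, spec$total_params), call. = FALSE)
  structure(list(spec = spec, arch = arch,
                 weights = cpp_net_init(arch, as.integer(seed)),
                 state = cpp_net_init_state(arch),
                 loss_trace = numeric(0), trained = FALSE),
            class = "lbfcn_model")
}

#' Number of trainable parameters held by a model
#'
#' @param model An `lbfcn_model`.
#' @return The length of the engine's weight vector.
#' @export
model_param_count <- function(model) length(model$weights)

#' @export
print.lbfcn_model <- function(x, ...) {
  cat(sprintf("<lbfcn_model> %s, %s parameters, %s\n",
              paste(x$spec$input_shape, collapse = "x"),
              format(length(x$weights), big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs)", length(x$loss_trace)) else "untrained"))
  invisible(x)
}

#' Class probabilities for a batch of images
#'
#' Forward pass in inference mode (batch-norm running statistics).
#'
#' @param object An `lbfcn_model`.
#' @param x Array `(n, size, size, channels)` of preprocessed images.
#' @param ... Unused.
#' @return `n x 3` matrix of class probabilities (columns in
#'   [scint_classes()] order), rows summing to 1.
#' @export
predict.lbfcn_model <- function(object, x, ...) {
  p <- cpp_net_predict(object$arch, object$weights, object$state, x)
  colnames(p) <- scint_classes()
  p
}

#' Serialize a network specification
#'
#' `network_spec_json` dumps the full specification (blocks, layer table,
#' totals) as JSON; `write_layer_table` exports the per-layer audit table as
#' CSV.
#'
#' @param spec A `network_spec`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
network_spec_json <- function(spec, path) {
  jsonlite::write_json(list(input_shape = spec$input_shape,
                            residual_count = spec$residual_count,
                            total_params = spec$total_params, flops = spec$flops,
                            layers = spec$layers),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname network_spec_json
#' @export
write_layer_table <- function(spec, path) {
  write.csv(spec$layers, path, row.names = FALSE)
  invisible(path)
}
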