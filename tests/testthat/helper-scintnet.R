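# Shared fixtures: small, fast phantom configurations used across tests.

small_phantom <- function(seed = 1L, ...) {
  phantom_config(image_height = 128L, image_width = 32L,
                 class_counts = c(malignant = 4L, degenerative = 4L, normal = 4L),
                 seed = seed, ...)
}

tiny_spec <- function(input_size = 16L, channels = 1L) {
  build_lbfcn_light(channels = channels, input_size = input_size,
                    filters = c(2L, 3L, 2L, 2L))
}

# Independent metric recount straight from label pairs (the brute-force
# oracle the confusion-matrix pipeline is checked against).
oracle_metrics <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  tn <- sum(truth != cls & pred != cls)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  spec <- if (fp + tn == 0) 0 else tn / (fp + tn)
  c(precision = prec, recall = rec, f1 = f1, sensitivity = rec,
    specificity = spec, counts_sum = tp + fp + tn + fn)
}
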