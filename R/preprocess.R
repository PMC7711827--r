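#' Preprocessing configuration
#'
#' The curation chain applied to every image before it reaches the network:
#' grayscale conversion, aspect-preserving bilinear resize to a square
#' `target_size` with centered zero padding, fixed-scale normalization to
#' `[0, 1]`, and (during training only) minimal rotation/rescale
#' augmentation.
#'
#' @param target_size Square network resolution in px (default 224).
#' @param rotation_max_deg Maximum augmentation rotation, degrees (default
#'   10; the protocol prescribes "minimal" augmentation without a number).
#' @param rescale_range Multiplicative zoom interval (default 0.9-1.1).
#' @param channels 1 keeps a single grayscale plane; 3 replicates it, the
#'   default input depth of the network.
#' @param augment Enable augmentation when the pipeline trains.
#' @param bit_depth Source bit depth governing the fixed normalization
#'   divisor (`2^bit_depth - 1`; default 16 for the phantom's count PNGs).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, rotation_max_deg = 10,
                              rescale_range = c(0.9, 1.1), channels = 3L,
                              augment = TRUE, bit_depth = 16L) {
  stopifnot(target_size > 0, rotation_max_deg >= 0, all(rescale_range > 0),
            channels %in% c(1L, 3L))
  structure(list(target_size = as.integer(target_size),
                 rotation_max_deg = rotation_max_deg,
                 rescale_range = rescale_range, channels = as.integer(channels),
                 augment = augment, bit_depth = as.integer(bit_depth)),
            class = "preprocess_config")
}

#' Convert an image to a single grayscale plane
#'
#' Three-channel input is reduced with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114); single-plane input is returned unchanged.
#'
#' @param image A matrix (H x W) or array (H x W x 1 or H x W x 3).
#' @return A matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] == 1) return(image[, , 1])
  if (length(d) == 3 && d[3] == 3)
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  stop("expected a 1- or 3-channel image", call. = FALSE)
}

#' Aspect-preserving resize with centered zero padding
#'
#' Scales the longer side to `target_size` (bilinear), scales the shorter
#' side by the same factor, and centers the result on a zero square canvas;
#' when the padding is odd the extra pixel goes to the trailing side.  A
#' 1024 x 256 scintigram at target 224 yields a 224 x 56 content region
#' with 84 zero columns on each side.
#'
#' @param image Numeric matrix.
#' @param target_size Output side length in px.
#' @return `target_size x target_size` matrix with attributes
#'   `content_height`/`content_width` describing the content region.
#' @export
resize_pad <- function(image, target_size) {
  H <- nrow(image); W <- ncol(image)
  if (H < 1 || W < 1) stop("zero-sized input image", call. = FALSE)
  scale <- target_size / max(H, W)
  h2 <- max(1L, as.integer(round(H * scale)))
  w2 <- max(1L, as.integer(round(W * scale)))
  if (H >= W) h2 <- as.integer(target_size) else w2 <- as.integer(target_size)
  content <- cpp_resize_bilinear(image, h2, w2)
  out <- matrix(0, target_size, target_size)
  top <- (target_size - h2) %/% 2
  left <- (target_size - w2) %/% 2
  out[top + seq_len(h2), left + seq_len(w2)] <- content
  attr(out, "content_height") <- h2
  attr(out, "content_width") <- w2
  out
}

#' Fixed-scale pixel normalization
#'
#' Divides by the representable maximum of the source bit depth (65535 for
#' 16-bit data), not by the per-image maximum, so inter-image intensity
#' information — which hotspot classification relies on — is preserved.
#'
#' @param image Nonnegative numeric matrix or array.
#' @param bit_depth Source bit depth (divisor is `2^bit_depth - 1`); use
#'   `bit_depth = 0` for data already on the unit scale (identity, making
#'   the operation idempotent).
#' @return The image scaled into `[0, 1]`.
#' @export
normalize_pixels <- function(image, bit_depth = 16L) {
  if (any(image < 0)) stop("negative pixel values", call. = FALSE)
  if (bit_depth == 0) return(image)
  pmin(image / (2^bit_depth - 1), 1)
}

#' Rotation/rescale augmentation
#'
#' Applies a rotation with angle drawn uniformly from
#' `[-rotation_max_deg, +rotation_max_deg]` about the image center and an
#' isotropic zoom drawn from `rescale_range`, bilinear with zero fill; the
#' label is unchanged and the output shape equals the input shape.
#'
#' @param image Numeric matrix.
#' @param label Class label, passed through untouched.
#' @param config A [preprocess_config()].
#' @return List with elements `image` and `label`.
#' @export
augment_image <- function(image, label, config) {
  ang <- runif(1, -config$rotation_max_deg, config$rotation_max_deg)
  zoom <- runif(1, config$rescale_range[1], config$rescale_range[2])
  list(image = cpp_rotate_zoom(image, ang, zoom), label = label)
}

#' Run the full curation chain on a dataset
#'
#' Grayscale -> resize/pad -> normalize for every record, replicating the
#' single plane onto `channels` planes.  Augmentation is not applied here:
#' the training loop augments online, per image per epoch.
#'
#' @param dataset A `synthetic_dataset` with pixel grids.
#' @param config A [preprocess_config()].
#' @return List with `x`, an array `(n, target_size, target_size, channels)`,
#'   and `y`, the integer class vector (0 = normal, 1 = malignant,
#'   2 = degenerative).
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  n <- length(dataset$records)
  s <- config$target_size
  x <- array(0, dim = c(n, s, s, config$channels))
  for (i in seq_len(n)) {
    img <- to_grayscale(dataset$records[[i]]$pixels)
    img <- resize_pad(img, s)
    img <- normalize_pixels(img, config$bit_depth)
    for (ch in seq_len(config$channels)) x[i, , , ch] <- img
  }
  y <- class_index(dataset$manifest$label)
  list(x = x, y = y)
}

#' Class label encoding
#'
#' The fixed class order of the package: normal = 0, malignant = 1,
#' degenerative = 2.
#'
#' @param labels Character vector of labels.
#' @return Integer vector of 0-based class indices.
#' @export
class_index <- function(labels) {
  lv <- scint_classes()
  idx <- match(labels, lv) - 1L
  if (anyNA(idx)) stop("unknown class label(s): ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

#' @rdname class_index
#' @export
scint_classes <- function() c("normal", "malignant", "degenerative")
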