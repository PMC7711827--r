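#' Phantom generator configuration
#'
#' Parameters of the synthetic whole-body scintigram generator.  Defaults
#' reproduce the composition of the reference clinical dataset: 778 planar
#' views at 1024 x 256 px split 328 malignant / 271 degenerative / 179
#' normal, with metastatic focal uptake 2.5-6.0 x local background,
#' degenerative joint uptake 1.5-2.5 x, and Poisson counting noise around a
#' mean background of 40 counts per pixel.
#'
#' @param image_height,image_width Image geometry in pixels.
#' @param class_counts Named integer vector with elements `malignant`,
#'   `degenerative`, `normal`.
#' @param lesion_rate Poisson mean of the focal-lesion count per malignant
#'   image; the draw is truncated to be at least 1 (a malignant image must
#'   contain a lesion).
#' @param lesion_intensity_range Uptake multiplier interval for metastatic
#'   foci, relative to local background.
#' @param degenerative_intensity_range Uptake multiplier interval for joint
#'   and spine degenerative changes.
#' @param lesion_radius_frac Interval for the focal-lesion radius, as a
#'   fraction of `image_height` (defaults 0.8-2 percent, i.e. 8-20 px at
#'   full 1024-row geometry).
#' @param noise_scale Mean background photon count per pixel; pixel values
#'   are Poisson draws with mean `noise_scale` x relative uptake.  Zero
#'   disables counting noise.
#' @param artifact_prob Per-image probability of one injection-site or
#'   bladder artifact (never changes the class label).
#' @param difficulty `"easy"` keeps the two intensity ranges disjoint with a
#'   safety margin (degenerative capped at the metastatic minimum minus 0.5);
#'   `"hard"` extends the degenerative range past the metastatic minimum so
#'   the classes overlap.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   bit-identical dataset.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 1024L, image_width = 256L,
                           class_counts = c(malignant = 328L, degenerative = 271L, normal = 179L),
                           lesion_rate = 5, lesion_intensity_range = c(2.5, 6.0),
                           degenerative_intensity_range = c(1.5, 2.5),
                           lesion_radius_frac = c(0.008, 0.02),
                           noise_scale = 40, artifact_prob = 0.3,
                           difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              class_counts = class_counts, lesion_rate = lesion_rate,
              lesion_intensity_range = lesion_intensity_range,
              degenerative_intensity_range = degenerative_intensity_range,
              lesion_radius_frac = lesion_radius_frac,
              noise_scale = noise_scale, artifact_prob = artifact_prob,
              difficulty = difficulty, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_height < 32 || cfg$image_width < 16)
    stop("phantom geometry must be at least 32 x 16 px", call. = FALSE)
  cls <- c("malignant", "degenerative", "normal")
  if (!all(cls %in% names(cfg$class_counts)))
    stop("class_counts must name malignant, degenerative and normal", call. = FALSE)
  if (any(cfg$class_counts < 0)) stop("class counts must be non-negative", call. = FALSE)
  if (cfg$lesion_rate <= 0) stop("lesion_rate must be positive", call. = FALSE)
  for (rg in list(cfg$lesion_intensity_range, cfg$degenerative_intensity_range)) {
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 1)
      stop("intensity ranges must be increasing intervals with lower bound >= 1", call. = FALSE)
  }
  if (cfg$noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  if (cfg$artifact_prob < 0 || cfg$artifact_prob > 1)
    stop("artifact_prob must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# Effective sampling ranges once the difficulty margin is applied.  In easy
# mode the degenerative interval is capped 0.5 below the metastatic minimum
# (ranges disjoint by construction); in hard mode it is extended 0.7 past it.
effective_ranges <- function(cfg) {
  met <- cfg$lesion_intensity_range
  deg <- cfg$degenerative_intensity_range
  if (cfg$difficulty == "easy") {
    deg[2] <- min(deg[2], met[1] - 0.5)
  } else {
    deg[2] <- max(deg[2], met[1] + 0.7)
  }
  deg[2] <- max(deg[2], deg[1])
  list(metastatic = met, degenerative = deg)
}

#' Anatomical anchor table
#'
#' Fixed, versioned coordinate table of the schematic whole-body phantom, in
#' fractions of the image height/width.  All paired structures are mirrored
#' exactly about the silhouette midline (`col_right = 1 - col_left`).
#'
#' @return A list with components `axial` (candidate metastasis sites,
#'   matrix of row/col fractions), `joints` (data frame of bilaterally
#'   paired joint sites), `spine` (row extent and column band of the spine),
#'   and `artifact` sites.
#' @export
scint_anchors <- function() {
  spine_rows <- seq(0.13, 0.48, by = 0.05)
  axial <- rbind(
    cbind(spine_rows, 0.50),                     # vertebral column
    c(0.050, 0.50),                              # skull
    c(0.200, 0.50),                              # sternum
    c(0.180, 0.38), c(0.180, 0.62),              # upper ribs
    c(0.240, 0.35), c(0.240, 0.65),
    c(0.300, 0.36), c(0.300, 0.64),              # lower ribs
    c(0.440, 0.34), c(0.440, 0.66),              # iliac wings
    c(0.480, 0.42), c(0.480, 0.58),              # sacro-iliac region
    c(0.540, 0.34), c(0.540, 0.66),              # femoral heads
    c(0.155, 0.22), c(0.155, 0.78)               # proximal humeri
  )
  colnames(axial) <- c("row", "col")
  joints <- data.frame(
    name = c("shoulder", "wrist", "hand", "knee", "ankle", "foot", "hip"),
    row = c(0.145, 0.445, 0.495, 0.720, 0.905, 0.950, 0.530),
    col_left = c(0.185, 0.125, 0.125, 0.365, 0.355, 0.330, 0.340),
    stringsAsFactors = FALSE
  )
  joints$col_right <- 1 - joints$col_left
  list(axial = axial, joints = joints,
       spine = list(rows = c(0.10, 0.50), cols = c(0.47, 0.53)),
       artifact = list(injection = data.frame(row = c(0.42, 0.42), col = c(0.125, 0.875)),
                       bladder = c(row = 0.49, col = 0.50)))
}

# Silhouette mask and relative-uptake template are deterministic functions of
# the geometry (no RNG use), so the expected normal pattern can be
# reconstructed exactly by any consumer.
silhouette_mask <- function(H, W) {
  r <- matrix(seq_len(H) / H, H, W)
  c_ <- matrix(rep(seq_len(W) / W, each = H), H, W)
  m <- ((r - 0.055) / 0.050)^2 + ((c_ - 0.5) / 0.13)^2 <= 1          # head
  m <- m | (r >= 0.09 & r <= 0.13 & c_ >= 0.44 & c_ <= 0.56)         # neck
  m <- m | (r >= 0.12 & r <= 0.42 & c_ >= 0.26 & c_ <= 0.74)         # torso
  m <- m | (r >= 0.12 & r <= 0.17 & c_ >= 0.16 & c_ <= 0.84)         # shoulder girdle
  m <- m | (r >= 0.14 & r <= 0.52 & ((c_ >= 0.08 & c_ <= 0.18) |
                                     (c_ >= 0.82 & c_ <= 0.92)))     # arms
  m <- m | (r >= 0.40 & r <= 0.56 & c_ >= 0.24 & c_ <= 0.76)         # pelvis
  m <- m | (r >= 0.50 & r <= 0.97 & ((c_ >= 0.28 & c_ <= 0.45) |
                                     (c_ >= 0.55 & c_ <= 0.72)))     # legs
  m <- m | (r >= 0.93 & r <= 0.97 & ((c_ >= 0.24 & c_ <= 0.45) |
                                     (c_ >= 0.55 & c_ <= 0.76)))     # feet
  m
}

# Multiplicative Gaussian patch, applied in place on a relative-uptake grid.
apply_blob <- function(u, H, W, row0, col0, sigma_r, sigma_c, factor) {
  # restrict evaluation to a 4-sigma bounding box for speed
  i0 <- max(1L, floor(row0 - 4 * sigma_r)); i1 <- min(H, ceiling(row0 + 4 * sigma_r))
  j0 <- max(1L, floor(col0 - 4 * sigma_c)); j1 <- min(W, ceiling(col0 + 4 * sigma_c))
  if (i0 > i1 || j0 > j1) return(u)
  ii <- i0:i1; jj <- j0:j1
  g <- exp(-outer((ii - row0)^2 / (2 * sigma_r^2), (jj - col0)^2 / (2 * sigma_c^2), `+`))
  u[ii, jj] <- u[ii, jj] * (1 + (factor - 1) * g)
  u
}

#' Build the normal skeletal uptake template
#'
#' Deterministic body-silhouette grid of relative uptake: baseline 1 inside
#' the silhouette, zero outside, with elevated uptake at the documented
#' anchor sites (spine band, pelvis, skull, paired joints, kidneys,
#' bladder).  Posterior views carry a stronger renal signature.
#'
#' @param config A [phantom_config()].
#' @param view `"anterior"` or `"posterior"`.
#' @return A `image_height x image_width` matrix of relative uptake.
#' @export
generate_body_template <- function(config, view = c("anterior", "posterior")) {
  view <- match.arg(view)
  validate_phantom_config(config)
  H <- config$image_height; W <- config$image_width
  u <- ifelse(silhouette_mask(H, W), 1, 0)
  r <- matrix(seq_len(H) / H, H, W)
  c_ <- matrix(rep(seq_len(W) / W, each = H), H, W)
  u[r >= 0.10 & r <= 0.50 & c_ >= 0.47 & c_ <= 0.53] <-
    u[r >= 0.10 & r <= 0.50 & c_ >= 0.47 & c_ <= 0.53] * 1.5          # spine band
  u[r >= 0.41 & r <= 0.50 & c_ >= 0.30 & c_ <= 0.70] <-
    u[r >= 0.41 & r <= 0.50 & c_ >= 0.30 & c_ <= 0.70] * 1.3          # pelvic band
  u[((r - 0.055) / 0.050)^2 + ((c_ - 0.5) / 0.13)^2 <= 1] <-
    u[((r - 0.055) / 0.050)^2 + ((c_ - 0.5) / 0.13)^2 <= 1] * 1.25    # skull
  kidney_f <- if (view == "posterior") 1.6 else 1.35
  bladder_f <- if (view == "posterior") 1.35 else 1.5
  blobs <- rbind(
    c(0.330, 0.40, 0.020, 0.040, kidney_f), c(0.330, 0.60, 0.020, 0.040, kidney_f),
    c(0.490, 0.50, 0.015, 0.040, bladder_f),
    c(0.145, 0.185, 0.012, 0.030, 1.4), c(0.145, 0.815, 0.012, 0.030, 1.4),  # shoulders
    c(0.720, 0.365, 0.010, 0.025, 1.3), c(0.720, 0.635, 0.010, 0.025, 1.3),  # knees
    c(0.445, 0.125, 0.008, 0.020, 1.2), c(0.445, 0.875, 0.008, 0.020, 1.2),  # wrists
    c(0.905, 0.355, 0.008, 0.020, 1.2), c(0.905, 0.645, 0.008, 0.020, 1.2)   # ankles
  )
  for (q in seq_len(nrow(blobs)))
    u <- apply_blob(u, H, W, blobs[q, 1] * H, blobs[q, 2] * W,
                    blobs[q, 3] * H, blobs[q, 4] * W, blobs[q, 5])
  u[u > 0 & u < 1] <- 1   # blob skirts never dip below baseline inside the body
  u
}

new_scintigram <- function(pixels, view, label, lesions, config) {
  structure(list(pixels = pixels, view = view, label = label,
                 lesions = lesions, config = config),
            class = "scintigram")
}

empty_lesions <- function() {
  data.frame(row = numeric(0), col = numeric(0), radius_px = numeric(0),
             intensity_multiplier = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)
}

# Snap a jittered anchor back onto the silhouette if the jitter escaped it.
snap_inside <- function(mask, row, col, row0, col0) {
  H <- nrow(mask); W <- ncol(mask)
  row <- min(max(round(row), 1), H); col <- min(max(round(col), 1), W)
  if (mask[row, col]) c(row, col) else c(round(row0), round(col0))
}

#' Place metastatic focal lesions on a template
#'
#' Draws a truncated-Poisson number of compact Gaussian-profile hot foci
#' (`N ~ Poisson(lesion_rate)` conditioned on `N >= 1`) at jittered
#' axial-skeleton anchor sites, with uptake multipliers from the metastatic
#' intensity range.
#'
#' @param template Relative-uptake grid from [generate_body_template()].
#' @param config A [phantom_config()].
#' @param view View label carried into the record.
#' @return A `scintigram` with label `"malignant"` (pre-noise).
#' @export
place_metastatic_lesions <- function(template, config, view = "anterior") {
  H <- nrow(template); W <- ncol(template)
  anchors <- scint_anchors()$axial
  if (nrow(anchors) == 0) stop("empty axial anchor set", call. = FALSE)
  mask <- template > 0
  n <- 0
  while (n < 1) n <- rpois(1, config$lesion_rate)
  rg <- effective_ranges(config)$metastatic
  idx <- sample.int(nrow(anchors), n, replace = n > nrow(anchors))
  les <- empty_lesions()
  u <- template
  for (q in seq_len(n)) {
    a <- anchors[idx[q], ]
    row0 <- a["row"] * H; col0 <- a["col"] * W
    pt <- snap_inside(mask, row0 + runif(1, -0.012, 0.012) * H,
                      col0 + runif(1, -0.025, 0.025) * W, row0, col0)
    m <- runif(1, rg[1], rg[2])
    radius <- runif(1, config$lesion_radius_frac[1], config$lesion_radius_frac[2]) * H
    u <- apply_blob(u, H, W, pt[1], pt[2], radius / 2, radius / 2, m)
    les <- rbind(les, data.frame(row = pt[1], col = pt[2], radius_px = radius,
                                 intensity_multiplier = m, kind = "metastatic"))
  }
  new_scintigram(u, view, "malignant", les, config)
}

#' Place degenerative joint and spine changes on a template
#'
#' Selects 1-4 joint pairs from the anchor table and applies bilaterally
#' symmetric moderate uptake (same multiplier on both sides, mirrored
#' columns), plus an optional short spine segment, with multipliers from the
#' degenerative intensity range.
#'
#' @inheritParams place_metastatic_lesions
#' @return A `scintigram` with label `"degenerative"` (pre-noise).
#' @export
place_degenerative_changes <- function(template, config, view = "anterior") {
  H <- nrow(template); W <- ncol(template)
  joints <- scint_anchors()$joints
  rg <- effective_ranges(config)$degenerative
  npair <- sample.int(4, 1)
  sel <- sample.int(nrow(joints), min(npair, nrow(joints)))
  les <- empty_lesions()
  u <- template
  for (q in sel) {
    m <- runif(1, rg[1], rg[2])
    radius <- 1.3 * runif(1, config$lesion_radius_frac[1], config$lesion_radius_frac[2]) * H
    for (side in c("col_left", "col_right")) {
      row0 <- joints$row[q] * H; col0 <- joints[[side]][q] * W
      u <- apply_blob(u, H, W, row0, col0, radius / 2, radius / 2, m)
      les <- rbind(les, data.frame(row = row0, col = col0, radius_px = radius,
                                   intensity_multiplier = m, kind = "degenerative"))
    }
  }
  if (runif(1) < 0.5) {   # degenerative spine segment
    m <- runif(1, rg[1], rg[2])
    row0 <- runif(1, 0.15, 0.45) * H
    u <- apply_blob(u, H, W, row0, 0.5 * W, 0.02 * H, 0.03 * W, m)
    les <- rbind(les, data.frame(row = row0, col = 0.5 * W, radius_px = 0.02 * H,
                                 intensity_multiplier = m, kind = "degenerative"))
  }
  new_scintigram(u, view, "degenerative", les, config)
}

#' Apply scintigraphic counting noise and acquisition artifacts
#'
#' Replaces every pixel by a Poisson draw with mean
#' `noise_scale x relative uptake` (standard gamma-camera counting
#' statistics); with probability `artifact_prob` one artifact blob is first
#' added to the uptake grid (injection site at a forearm anchor, or a
#' bladder hot region).  Artifacts are recorded with kind `"artifact"` and
#' never change the label.  With `noise_scale = 0` the uptake grid is
#' returned unchanged apart from artifacts.
#'
#' @param scint A pre-noise `scintigram`.
#' @param config A [phantom_config()].
#' @return The `scintigram` with `pixels` holding count data.
#' @export
add_acquisition_noise <- function(scint, config) {
  if (config$noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  u <- scint$pixels
  H <- nrow(u); W <- ncol(u)
  if (runif(1) < config$artifact_prob) {
    art <- scint_anchors()$artifact
    if (runif(1) < 0.5) {
      site <- art$injection[sample.int(nrow(art$injection), 1), ]
      m <- runif(1, 4, 8); sr <- 0.008 * H
    } else {
      site <- as.list(art$bladder)
      m <- runif(1, 3, 5); sr <- 0.02 * H
    }
    u <- apply_blob(u, H, W, site$row * H, site$col * W, sr, sr, m)
    scint$lesions <- rbind(scint$lesions,
                           data.frame(row = site$row * H, col = site$col * W,
                                      radius_px = sr * 2, intensity_multiplier = m,
                                      kind = "artifact"))
  }
  if (config$noise_scale > 0) {
    counts <- rpois(length(u), config$noise_scale * u)
    u <- matrix(counts, H, W)
  }
  scint$pixels <- u
  scint
}

#' @export
print.scintigram <- function(x, ...) {
  cat(sprintf("<scintigram> %dx%d px, view %s, label %s, %d lesion(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$view, x$label, nrow(x$lesions)))
  invisible(x)
}

record_seed <- function(seed, i) (abs(seed) + 7919L * i) %% 2147483647L

generate_record <- function(config, label, view) {
  template <- generate_body_template(config, view)
  s <- switch(label,
    malignant = place_metastatic_lesions(template, config, view),
    degenerative = place_degenerative_changes(template, config, view),
    normal = new_scintigram(template, view, "normal", empty_lesions(), config))
  add_acquisition_noise(s, config)
}

#' Generate a synthetic scintigram dataset
#'
#' Produces exactly `class_counts` records per class, each a single anterior
#' or posterior view, deterministically under `config$seed` (every record
#' has its own derived sub-seed, so the result is independent of generation
#' order).  Optionally writes the dataset to disk as 16-bit grayscale PNGs
#' with a CSV manifest and a YAML config echo.
#'
#' @param config A [phantom_config()].
#' @param dir Optional output directory for PNGs + manifest.
#' @param keep_pixels Keep pixel grids in memory (set `FALSE` with `dir` for
#'   large geometries to bound memory).
#' @return A `synthetic_dataset`: list of `records`, a `manifest` data frame
#'   (filename, label, view, seed_id) and the generating `config`.
#' @export
generate_dataset <- function(config, dir = NULL, keep_pixels = TRUE) {
  validate_phantom_config(config)
  counts <- config$class_counts[c("malignant", "degenerative", "normal")]
  labels <- rep(names(counts), counts)
  n <- length(labels)
  manifest <- data.frame(filename = sprintf("scint_%05d.png", seq_len(n)),
                         label = labels,
                         view = character(n), seed_id = integer(n),
                         stringsAsFactors = FALSE)
  if (!is.null(dir) && n > 0) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- record_seed(config$seed, i)
    set.seed(sid)
    view <- if (runif(1) < 0.5) "anterior" else "posterior"
    rec <- generate_record(config, labels[i], view)
    manifest$view[i] <- view
    manifest$seed_id[i] <- sid
    if (!is.null(dir))
      write_png16(file.path(dir, manifest$filename[i]), round(rec$pixels))
    if (keep_pixels) records[[i]] <- rec else {
      rec$pixels <- NULL
      records[[i]] <- rec
    }
  }
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    writeLines(yaml::as.yaml(unclass(config)), file.path(dir, "config.yml"))
  }
  structure(list(records = records, manifest = manifest, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d records (%s), %dx%d px\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$label)),
                            as.integer(table(x$manifest$label))), collapse = ", "),
              x$config$image_height, x$config$image_width))
  invisible(x)
}

#' Read a scintigram dataset from disk
#'
#' Loads a directory written by [generate_dataset()] (or any directory of
#' grayscale PNGs with a compatible `manifest.csv`).
#'
#' @param dir Dataset directory.
#' @return A `synthetic_dataset` with count-valued pixel grids.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("missing manifest: ", mf, call. = FALSE)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  cfgf <- file.path(dir, "config.yml")
  config <- if (file.exists(cfgf)) {
    cl <- yaml::yaml.load_file(cfgf)
    cl$class_counts <- unlist(cl$class_counts)
    cl$lesion_intensity_range <- unlist(cl$lesion_intensity_range)
    cl$degenerative_intensity_range <- unlist(cl$degenerative_intensity_range)
    cl$lesion_radius_frac <- unlist(cl$lesion_radius_frac)
    structure(cl, class = "phantom_config")
  } else NULL
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- read_png16(file.path(dir, manifest$filename[i]))
    new_scintigram(px, manifest$view[i], manifest$label[i], empty_lesions(), config)
  })
  structure(list(records = records, manifest = manifest, config = config),
            class = "synthetic_dataset")
}

#' Write / read 16-bit grayscale PNG
#'
#' Thin wrappers over the package's internal PNG codec.  `write_png16`
#' stores an integer count matrix at 16-bit depth (values clipped to
#' 0-65535) with deterministic compression, so identical inputs produce
#' byte-identical files.
#'
#' @param path File path.
#' @param pixels Integer-valued matrix of counts.
#' @return `read_png16` returns an integer matrix.
#' @export
write_png16 <- function(path, pixels) {
  storage.mode(pixels) <- "integer"
  cpp_write_png16(path, pixels)
  invisible(path)
}

#' @rdname write_png16
#' @export
read_png16 <- function(path) cpp_read_png16(path)

# 3x3 box smoothing with edge replication; cheap shift-and-add.
box3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  up <- x[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- x[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  v <- x + up + dn
  lf <- v[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- v[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  (v + lf + rt) / 9
}

#' Rule-based hotspot classifier
#'
#' A deliberately simple, hand-coded reference detector used to establish
#' that the synthetic classes are separable before any network is involved.
#' It divides the (3x3-smoothed) count image by the expected normal pattern
#' `noise_scale x template`, so anchor-site elevations cancel, then applies
#' two thresholds derived from the configured intensity ranges: a high
#' threshold over the axial-skeleton region (metastases; artifact-prone
#' zones are excluded) and a bilateral joint score (minimum of the two
#' mirrored joint-disk means, which an unilateral artifact cannot fake).
#'
#' @param pixels Count matrix of one record.
#' @param view View of the record (selects the matching template).
#' @param config The generating [phantom_config()].
#' @return Predicted label, one of `"normal"`, `"malignant"`,
#'   `"degenerative"`.
#' @export
hotspot_rule_classifier <- function(pixels, view, config) {
  H <- nrow(pixels); W <- ncol(pixels)
  template <- generate_body_template(config, view)
  expected <- pmax(config$noise_scale * template, 1e-9)
  if (config$noise_scale == 0) expected <- pmax(template, 1e-9)
  ratio <- box3(pixels) / box3(expected)
  r <- matrix(seq_len(H) / H, H, W)
  c_ <- matrix(rep(seq_len(W) / W, each = H), H, W)
  det <- template > 0 & r > 0.03 & r < 0.60 & c_ > 0.22 & c_ < 0.78
  det <- det & !(((r - 0.49) * H)^2 + ((c_ - 0.50) * W)^2 < (0.035 * H)^2)  # bladder
  rg <- effective_ranges(config)
  # attenuation of a Gaussian peak under the 3x3 box at the minimum lesion sigma
  smin <- config$lesion_radius_frac[1] * H / 2
  att <- ((1 + 2 * exp(-1 / (2 * smin^2))) / 3)^2
  thr_hi <- 1 + (rg$metastatic[1] - 1) * att * 0.85
  thr_mid <- 1 + (rg$degenerative[1] - 1) * 0.60
  m_score <- max(ratio[det])
  joints <- scint_anchors()$joints
  rad <- 1.3 * mean(config$lesion_radius_frac) * H / 2
  jscore <- 0
  for (q in seq_len(nrow(joints))) {
    sides <- numeric(2)
    for (s in 1:2) {
      col0 <- (if (s == 1) joints$col_left[q] else joints$col_right[q]) * W
      row0 <- joints$row[q] * H
      d <- ((r * H - row0)^2 + (c_ * W - col0)^2) < rad^2
      sides[s] <- if (any(d)) mean(ratio[d]) else 0
    }
    jscore <- max(jscore, min(sides))
  }
  # mid-threshold evidence must cover a lesion-sized area, not a lone noisy px
  area_min <- max(10, round(3e-4 * H * W))
  mid_area <- sum(ratio[det] > thr_mid)
  if (m_score > thr_hi) "malignant"
  else if (jscore > thr_mid || mid_area >= area_min) "degenerative"
  else "normal"
}
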