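test_that("phantom config validation rejects bad settings", {
  expect_error(phantom_config(image_height = 0), "geometry")
  expect_error(phantom_config(class_counts = c(malignant = -1, degenerative = 1, normal = 1)),
               "non-negative")
  expect_error(phantom_config(artifact_prob = 1.5), "artifact_prob")
  expect_error(phantom_config(degenerative_intensity_range = c(0.5, 2)), "intensity")
  expect_error(phantom_config(noise_scale = -1), "noise_scale")
})

test_that("body template has the contracted support and scales with geometry", {
  cfg <- small_phantom()
  u <- generate_body_template(cfg)
  expect_equal(dim(u), c(128L, 32L))
  expect_true(all(u >= 0))
  mask <- silhouette_frac <- mean(u > 0)
  expect_gt(mean(u > 0), 0.15)          # a silhouette, not a full frame
  expect_lt(mean(u > 0), 0.75)
  # zero outside the silhouette, baseline >= 1 inside
  expect_true(all(u[u > 0] >= 1))
  # proportional scaling: halving the geometry halves the support box
  cfg2 <- phantom_config(image_height = 256L, image_width = 64L,
                         class_counts = cfg$class_counts)
  u2 <- generate_body_template(cfg2)
  expect_equal(dim(u2), c(256L, 64L))
  expect_equal(mean(u2 > 0), mean(u > 0), tolerance = 0.05)
  # deterministic: no RNG involvement
  expect_identical(u, generate_body_template(cfg))
})

test_that("metastatic placement respects truncation, ranges and the silhouette", {
  cfg <- small_phantom(seed = 3)
  u <- generate_body_template(cfg)
  mask <- u > 0
  set.seed(42)
  for (rep in 1:10) {
    s <- place_metastatic_lesions(u, cfg)
    expect_s3_class(s, "scintigram")
    expect_identical(s$label, "malignant")
    expect_gte(nrow(s$lesions), 1)                     # truncated at >= 1
    expect_true(all(s$lesions$kind == "metastatic"))
    m <- s$lesions$intensity_multiplier
    expect_true(all(m >= 2.5 & m <= 6.0))
    idx <- cbind(pmin(pmax(round(s$lesions$row), 1), nrow(u)),
                 pmin(pmax(round(s$lesions$col), 1), ncol(u)))
    expect_true(all(mask[idx]))
  }
})

test_that("truncated-Poisson lesion count matches the closed-form mean", {
  # closed form: E[N | N >= 1] = lambda / (1 - exp(-lambda)) = 5.0339 at lambda 5
  lambda <- 5
  truth <- lambda / (1 - exp(-lambda))
  set.seed(7)
  draws <- replicate(1e4, { n <- 0; while (n < 1) n <- rpois(1, lambda); n })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - truth), 3 * se)
  # and the generator's own lesion counts agree with the same law
  cfg <- small_phantom(seed = 9)
  u <- generate_body_template(cfg)
  set.seed(11)
  counts <- replicate(300, nrow(place_metastatic_lesions(u, cfg)$lesions))
  expect_lt(abs(mean(counts) - truth), 3 * sd(counts) / sqrt(length(counts)))
})

test_that("degenerative changes sit at joint anchors, bilaterally symmetric", {
  cfg <- small_phantom(seed = 5)
  u <- generate_body_template(cfg)
  W <- ncol(u)
  set.seed(1)
  for (rep in 1:10) {
    s <- place_degenerative_changes(u, cfg)
    expect_identical(s$label, "degenerative")
    joints <- s$lesions[s$lesions$kind == "degenerative", ]
    # joint lesions come in mirrored pairs about the midline (spine rows exempt)
    lat <- joints[abs(joints$col - W / 2) > 2, ]
    if (nrow(lat) > 0) {
      mirrored <- vapply(seq_len(nrow(lat)), function(i)
        any(abs((W + 1 - lat$col[i]) - lat$col) <= 2 & abs(lat$row - lat$row[i]) <= 1e-9),
        logical(1))
      expect_true(all(mirrored))
    }
    # easy difficulty: degenerative multipliers disjoint from metastatic range
    expect_true(all(joints$intensity_multiplier < 2.5))
  }
})

test_that("difficulty easy separates ranges, hard overlaps them", {
  easy <- scintnet:::effective_ranges(small_phantom(difficulty = "easy"))
  hard <- scintnet:::effective_ranges(small_phantom(difficulty = "hard"))
  expect_lt(easy$degenerative[2], easy$metastatic[1])
  expect_gt(hard$degenerative[2], hard$metastatic[1])
})

test_that("acquisition noise follows Poisson counting statistics", {
  cfg <- phantom_config(image_height = 100L, image_width = 100L,
                        class_counts = c(malignant = 1L, degenerative = 1L, normal = 1L),
                        artifact_prob = 0, noise_scale = 40)
  flat <- scintnet:::new_scintigram(matrix(1, 100, 100), "anterior", "normal",
                                    scintnet:::empty_lesions(), cfg)
  set.seed(12)
  noisy <- add_acquisition_noise(flat, cfg)
  v <- as.vector(noisy$pixels)          # 1e4 pixels at mean 40
  # Poisson: variance equals the mean; sample variance has SE ~ sqrt(2/(n-1)) * var
  expect_lt(abs(var(v) - mean(v)), 3 * sqrt(2 / (length(v) - 1)) * var(v))
  expect_lt(abs(mean(v) - 40), 3 * sqrt(40 / length(v)))
  # zero-noise limit returns the uptake grid unchanged
  cfg0 <- phantom_config(image_height = 100L, image_width = 100L,
                         class_counts = cfg$class_counts, artifact_prob = 0,
                         noise_scale = 0)
  expect_identical(add_acquisition_noise(flat, cfg0)$pixels, flat$pixels)
})

test_that("artifact probability zero yields no artifacts; artifacts keep labels", {
  cfg <- small_phantom(seed = 2, artifact_prob = 0)
  ds <- generate_dataset(cfg)
  kinds <- unlist(lapply(ds$records, function(r) r$lesions$kind))
  expect_false("artifact" %in% kinds)
  cfg1 <- small_phantom(seed = 2, artifact_prob = 1)
  ds1 <- generate_dataset(cfg1)
  expect_true(all(vapply(ds1$records, function(r) "artifact" %in% r$lesions$kind, logical(1))))
  expect_identical(ds1$manifest$label, ds$manifest$label)
})

test_that("generated datasets honor class counts, labels and determinism", {
  cfg <- small_phantom(seed = 31)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "synthetic_dataset")
  expect_identical(as.integer(table(ds$manifest$label)[c("malignant", "degenerative", "normal")]),
                   c(4L, 4L, 4L))
  # label consistent with lesion kinds present
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    kinds <- setdiff(unique(r$lesions$kind), "artifact")
    expected <- if ("metastatic" %in% kinds) "malignant"
                else if ("degenerative" %in% kinds) "degenerative" else "normal"
    expect_identical(r$label, expected)
    expect_identical(r$label, ds$manifest$label[i])
    expect_true(all(is.finite(r$pixels)) && all(r$pixels >= 0))
  }
  # bit-identical regeneration under the same config + seed
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds$records, `[[`, "pixels"),
                   lapply(ds2$records, `[[`, "pixels"))
  # empty dataset edge case
  ds0 <- generate_dataset(phantom_config(class_counts = c(malignant = 0L, degenerative = 0L, normal = 0L)))
  expect_identical(nrow(ds0$manifest), 0L)
})

test_that("on-disk datasets round-trip through 16-bit PNG byte-identically", {
  cfg <- small_phantom(seed = 17)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  ds <- generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  f1 <- file.path(d1, ds$manifest$filename[1])
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, ds$manifest$filename[1]))))
  back <- read_dataset(d1)
  expect_identical(nrow(back$manifest), nrow(ds$manifest))
  expect_equal(back$records[[1]]$pixels,
               matrix(as.integer(round(ds$records[[1]]$pixels)), nrow(ds$records[[1]]$pixels)),
               ignore_attr = TRUE)
  # our files are also readable by the independent png package
  ref <- png::readPNG(f1)
  expect_equal(round(ref * 65535), ds$records[[1]]$pixels, ignore_attr = TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a trivial hotspot rule separates easy-mode classes at >= 90%", {
  cfg <- phantom_config(image_height = 512L, image_width = 128L,
                        class_counts = c(malignant = 42L, degenerative = 35L, normal = 23L),
                        difficulty = "easy", seed = 42)
  ds <- generate_dataset(cfg)
  pred <- vapply(seq_along(ds$records), function(i)
    hotspot_rule_classifier(ds$records[[i]]$pixels, ds$records[[i]]$view, cfg), "")
  expect_gte(mean(pred == ds$manifest$label), 0.90)
})
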