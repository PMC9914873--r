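test_that("co-occurrence counts match hand enumeration and pair-count bookkeeping", {
  # each row is (0, 0, 200, 200); with 2 levels these quantize to (0, 0, 1, 1)
  img <- matrix(rep(c(0, 0, 200, 200), times = 4), 4, 4, byrow = TRUE)
  m <- glcm_matrix(img, distance = 1, angle = 0, levels = 2)
  expect_equal(m[1, 1], 4); expect_equal(m[1, 2], 4)
  expect_equal(m[2, 2], 4); expect_equal(m[2, 1], 0)
  mn <- glcm_matrix(img, 1, 0, levels = 2, normalize = TRUE)
  expect_equal(mn[1, 1], 1 / 3); expect_equal(mn[1, 2], 1 / 3)
  expect_equal(mn[2, 2], 1 / 3)

  const <- matrix(90, 6, 6)
  mc <- glcm_matrix(const, 1, 90, levels = 8, normalize = TRUE)
  lev <- floor(90 * 8 / 256) + 1
  expect_equal(mc[lev, lev], 1)
  expect_equal(sum(mc), 1)

  # unnormalized mass equals the number of in-bounds pairs for any offset
  for (s in 1:5) {
    img <- random_image(7, 9, seed = s)
    for (a in c(0, 45, 90, 135)) for (d in 1:2) {
      m <- glcm_matrix(img, d, a, levels = 16)
      n_expected <- (7 - d * (a != 0)) * (9 - d * (a != 90))
      expect_equal(sum(m), n_expected)
      expect_equal(attr(m, "n_pairs"), n_expected)
    }
  }

  # offset larger than the image is flagged empty
  tiny <- matrix(0:3, 2, 2)
  expect_true(attr(glcm_matrix(tiny, 5, 0, levels = 4), "empty"))
})

test_that("GLCM statistics match the brute-force oracle", {
  img <- matrix(rep(c(0, 0, 200, 200), times = 4), 4, 4, byrow = TRUE)
  feats <- glcm_features(img, glcm_config(distances = 1, angles = 0, levels = 2))
  expect_equal(unname(feats["glcm:d1.a0.contrast"]), 1 / 3)
  expect_equal(unname(feats["glcm:d1.a0.energy"]), 1 / 3)
  expect_equal(unname(feats["glcm:d1.a0.homogeneity"]), 5 / 6)

  const <- matrix(90, 8, 8)
  fc <- glcm_features(const, glcm_config(distances = 1, angles = 0, levels = 8))
  expect_equal(unname(fc), c(1, 1, 1, 0))  # energy, correlation, homogeneity, contrast

  for (s in 1:10) {
    img <- random_image(8, 8, seed = 100 + s)
    for (a in c(0, 45, 90, 135)) for (d in 1:2) {
      got <- glcm_features(img, glcm_config(distances = d, angles = a, levels = 8))
      want <- oracle_glcm_stats(img, d, a, levels = 8)
      expect_lt(max(abs(unname(got) - unname(want))), 1e-10)
    }
  }

  cfg <- glcm_config(distances = c(1, 2), angles = c(0, 45, 90, 135))
  expect_length(glcm_features(random_image(16, 16, 1), cfg), 32)
})

test_that("HOG length, zero-gradient and edge-orientation behaviour", {
  cfg <- hog_config()
  expect_length(hog_features(random_image(64, 64, 1), cfg), 1764)
  for (sz in list(c(64, 64), c(72, 64), c(80, 96), c(65, 67), c(128, 128))) {
    img <- random_image(sz[1], sz[2], seed = sum(sz))
    expect_length(hog_features(img, cfg), hog_length(sz[1], sz[2], cfg))
  }
  expect_error(hog_features(matrix(5, 10, 10), cfg), "block")

  expect_true(all(hog_features(matrix(33, 32, 32), cfg) == 0))

  # vertical step edge: horizontal gradient only, angle 0, all votes in bin 1
  edge <- step_edge_image(32, 32)
  v <- hog_features(edge, cfg)
  nz <- which(v != 0)
  expect_gt(length(nz), 0)
  expect_true(all((nz - 1) %% cfg$n_bins == 0))
  # per-pixel oracle: wherever the magnitude is nonzero the angle is 0
  gx <- edge[, c(2:32, 32)] - edge[, c(1, 1:31)]
  gy <- edge[c(2:32, 32), ] - edge[c(1, 1:31), ]
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  expect_true(all(ang[gx != 0 | gy != 0] == 0))

  vb <- hog_features(edge, hog_config(vote_mode = "bilinear"))
  expect_length(vb, length(v))
  expect_true(all(is.finite(vb)))
})

test_that("stub backbone embeddings are deterministic, shaped and linear at zero", {
  spec <- backbone_spec(input_size = 32, seed = 5)
  img <- random_image(64, 64, seed = 6)
  expect_identical(cnn_features(img, spec), cnn_features(img, spec))
  expect_length(cnn_features(img, spec), 16)
  expect_length(cnn_features(img, backbone_spec(input_size = 32, pooling = "flatten")),
                16 * 8 * 8)
  expect_true(all(cnn_features(matrix(0, 64, 64), spec) == 0))
  expect_error(cnn_features(img, backbone_spec(name = "vgg16",
                                               weights_source = "pretrained")),
               "not bundled")
  # different seeds give different trunks
  expect_false(identical(cnn_features(img, backbone_spec(input_size = 32, seed = 1)),
                         cnn_features(img, backbone_spec(input_size = 32, seed = 2))))
})

test_that("assembled feature vectors have a configuration-determined layout", {
  cfg4 <- feature_config(
    glcm = glcm_config(), hog = hog_config(),
    backbones = list(backbone_spec(name = "vgg16", input_size = 32, seed = 1),
                     backbone_spec(name = "densenet121", input_size = 32, seed = 2)))
  img <- random_image(64, 64, seed = 3)
  v <- assemble_features(img, cfg4)
  expect_identical(unique(sub(":.*", "", names(v))),
                   c("glcm", "hog", "vgg16", "densenet121"))
  expect_true(all(is.finite(v)))
  expect_false(anyDuplicated(names(v)) > 0)

  only_glcm <- feature_config(glcm = glcm_config(distances = c(1, 2)),
                              hog = NULL, backbones = list())
  expect_length(assemble_features(img, only_glcm), 32)

  # layout depends on the configuration, not on image content
  v2 <- assemble_features(random_image(64, 64, seed = 4), cfg4)
  expect_identical(names(v), names(v2))

  expect_error(feature_config(glcm = NULL, hog = NULL, backbones = list()),
               "at least one")

  tab <- extract_feature_table(list(img, random_image(32, 48, 9)),
                               only_glcm, resize_to = 32)
  expect_equal(dim(tab), c(2, 32))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, c("A", "B"), path)
  back <- read_feature_table(path)
  expect_equal(back$features, tab, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), c("A", "B"))
})
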