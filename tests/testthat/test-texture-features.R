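test_that("min-max normalization maps to [0,1] and flags constant FoVs", {
  f <- mp_fov(matrix(c(0, 2, 1, 1), 2, 2))
  n <- minmax_normalize(f)
  expect_equal(n$pixels, matrix(c(0, 1, 0.5, 0.5), 2, 2))
  expect_false(n$degenerate)

  const <- minmax_normalize(mp_fov(matrix(9, 3, 3)))
  expect_true(const$degenerate)
  expect_true(all(const$pixels == 0))

  # positive affine transforms normalize to the identical grid
  f2 <- tiny_fov()
  n1 <- minmax_normalize(f2)
  n2 <- minmax_normalize(mp_fov(3.7 * f2$pixels + 11, channel = f2$channel))
  expect_equal(n1$pixels, n2$pixels, tolerance = 1e-12)
})

test_that("first-order features match closed-form cases", {
  # half 0 / half 1 (checkerboard): mean .5, skew 0, kurtosis 1, entropy 1 bit
  checker <- mp_fov(outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 1.0)
  fo <- first_order_features(minmax_normalize(checker))
  expect_equal(unname(fo["mean"]), 0.5)
  expect_equal(unname(fo["skewness"]), 0)
  expect_equal(unname(fo["kurtosis"]), 1)
  expect_equal(unname(fo["entropy"]), 1)
  expect_equal(unname(fo["sd"]), sd(as.vector(checker$pixels)))

  # four equally filled histogram bins -> 2 bits
  vals <- rep(c(0, 0.3, 0.6, 0.9), each = 16)
  f4 <- list(pixels = matrix(vals / 0.9, 8, 8), degenerate = FALSE)
  expect_equal(unname(first_order_features(f4)["entropy"]), 2)

  # constant FoV: all-zero moments, no NaN
  fc <- first_order_features(minmax_normalize(mp_fov(matrix(5, 4, 4))))
  expect_equal(unname(fc[c("sd", "kurtosis", "skewness", "entropy")]), rep(0, 4))
})

test_that("quantization bins [0,1] uniformly with 1 in the top level", {
  expect_equal(as.vector(quantize(matrix(c(0, 0.49, 0.51, 1), 1, 4), 2)),
               c(0L, 0L, 1L, 1L))
  expect_equal(as.vector(quantize(matrix(c(0, 1 / 3, 2 / 3, 1), 1, 4), 4)),
               c(0L, 1L, 2L, 3L))
  set.seed(3)
  q <- quantize(matrix(runif(100), 10, 10), 8)
  expect_true(all(q %in% 0:7))
  expect_error(quantize(matrix(0.5, 2, 2), 1), class = "mptexture_validation_error")
})

test_that("GLCM matches hand-enumerated pairs and normalizes to unit mass", {
  g <- glcm(matrix(c(0L, 1L, 0L, 1L), 2, 2), 1, 0, levels = 2)
  expect_equal(unclass(g)[1:2, 1:2], matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)

  const <- glcm(matrix(2L, 4, 4), 1, 45, levels = 4)
  expect_equal(sum(const), 1)
  expect_equal(const[3, 3], 1)

  set.seed(9)
  img <- matrix(sample(0:5, 72, replace = TRUE), 8, 9)
  for (o in c(0, 45, 90, 135)) expect_equal(sum(glcm(img, 2, o, levels = 6)), 1)
  expect_error(glcm(matrix(0:3, 2, 2), 5, 0, levels = 4),
               class = "mptexture_validation_error")
})

test_that("GLCM equals the exhaustive pair-enumeration oracle", {
  set.seed(11)
  for (k in 1:40) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1); L <- sample(2:6, 1)
    img <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
    d <- sample(1:3, 1)
    for (o in c(0, 45, 90, 135)) {
      counts <- glcm(img, d, o, levels = L, normalize = FALSE)
      expect_identical(strip_mat(counts), glcm_oracle(img, d, o, L))
    }
  }
})

test_that("GLCM properties match direct evaluation and closed forms", {
  p <- structure(matrix(c(0.5, 0, 0, 0.5), 2, 2), normalized = TRUE)
  props <- glcm_properties(p)
  expect_equal(unname(props), c(0, 1, 0.5, 1), ignore_attr = TRUE)

  one <- structure(matrix(c(0, 0, 0, 1), 2, 2), normalized = TRUE)
  props1 <- glcm_properties(one)
  expect_equal(unname(props1[c("contrast", "energy", "homogeneity")]), c(0, 1, 1),
               ignore_attr = TRUE)
  expect_equal(unname(props1["correlation"]), 1, ignore_attr = TRUE)  # constant texture, flagged
  expect_true(attr(props1, "correlation_flagged"))

  L <- 5
  unif <- structure(matrix(1 / L^2, L, L), normalized = TRUE)
  expect_equal(unname(glcm_properties(unif)["energy"]), 1 / L^2, ignore_attr = TRUE)

  expect_error(glcm_properties(matrix(1, 2, 2)), class = "mptexture_validation_error")
})

test_that("channel vector has 13 parameters, is affine-invariant and in range", {
  cfg <- small_config()
  f <- tiny_fov()
  v <- channel_texture_vector(f, cfg)
  expect_length(v, 13)
  expect_named(v, feature_names(cfg))

  v2 <- channel_texture_vector(mp_fov(2.5 * f$pixels + 3, channel = "CARS"), cfg)
  expect_equal(v, v2, tolerance = 1e-12, ignore_attr = TRUE)

  expect_true(all(v[grep("energy", names(v))] > 0 & v[grep("energy", names(v))] <= 1))
  expect_true(all(v[grep("homogeneity", names(v))] > 0 & v[grep("homogeneity", names(v))] <= 1))
  expect_true(all(abs(v[grep("correlation", names(v))]) <= 1))
  expect_true(v["entropy"] >= 0 && v["entropy"] <= 8)
  expect_true(all(v[grep("contrast", names(v))] >= 0 &
                    v[grep("contrast", names(v))] <= (cfg$levels - 1)^2))

  expect_error(channel_texture_vector(tiny_fov(8, 8), texture_config()),
               class = "mptexture_validation_error")
})

test_that("orientation-averaged GLCM features are invariant to quarter turns", {
  cfg <- small_config()
  set.seed(5)
  px <- matrix(runif(40 * 40), 40, 40)
  v1 <- channel_texture_vector(mp_fov(px), cfg)
  rot <- t(px)[, rev(seq_len(40))]  # 90-degree rotation
  v2 <- channel_texture_vector(mp_fov(rot), cfg)
  glcm_idx <- grep("_d", names(v1))
  expect_equal(v1[glcm_idx], v2[glcm_idx], tolerance = 1e-9)
})

test_that("distances in um convert through pixel size", {
  # same physical texture sampled at 0.5 um/px must use doubled pixel distances
  cfg <- texture_config(distances_um = c(4, 8))
  f <- tiny_fov(60, 60, pixel_size_um = 0.5)
  v <- channel_texture_vector(f, cfg)  # 8 and 16 px internally
  expect_length(v, 13)
  # at 1 um/px a 60 px FoV cannot host no distance; verify error names distance
  f2 <- tiny_fov(6, 6, pixel_size_um = 1)
  expect_error(channel_texture_vector(f2, cfg), "8",
               class = "mptexture_validation_error")
})

test_that("combined vectors concatenate channels in declared order", {
  cfg <- small_config()
  f <- tiny_fov()
  v <- channel_texture_vector(f, cfg)
  both <- combine_vectors(list(CARS = v, TPEF = v))
  expect_length(both, 26)
  expect_named(both, c(feature_names(cfg, "CARS"), feature_names(cfg, "TPEF")))
  expect_length(combine_vectors(list(CARS = v)), 13)
  expect_length(combine_vectors(list(CARS = v, TPEF = v, SHG = v)), 39)
})

test_that("compute_features builds a provenance-keyed tibble from FoV sets", {
  cfg <- small_config()
  mk <- function(sid, gr, ch, seed) {
    set.seed(seed)
    mp_fov(matrix(runif(48 * 64), 48, 64), channel = ch, sample_id = sid,
           grid_row = gr)
  }
  fovsets <- list(
    list(CARS = mk("a", 0, "CARS", 1), TPEF = mk("a", 0, "TPEF", 2)),
    list(CARS = mk("a", 1, "CARS", 3), TPEF = mk("a", 1, "TPEF", 4))
  )
  ft <- compute_features(fovsets, cfg)
  expect_equal(nrow(ft), 2)
  expect_equal(sum(grepl("^(CARS|TPEF)_", names(ft))), 26)
  expect_equal(attr(ft, "config_hash"), cfg$hash)

  # mixed provenance within a set is refused
  bad <- list(list(CARS = mk("a", 0, "CARS", 1), TPEF = mk("b", 0, "TPEF", 2)))
  expect_error(compute_features(bad, cfg), class = "mptexture_validation_error")
})
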