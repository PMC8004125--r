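test_that("edge features behave on canonical images", {
  expect_equal(edge_features(matrix(7, 9, 9)),
               c(edge_frequency = 0, edge_contrast = 0,
                 edge_orientation_var = 0))
  # vertical step edge: all edge-pixel gradients share one orientation
  step <- cbind(matrix(0, 9, 4), matrix(200, 9, 5))
  ef <- edge_features(step)
  expect_gt(ef[["edge_frequency"]], 0)
  expect_equal(ef[["edge_orientation_var"]], 0, tolerance = 1e-12)
  # Sobel responses match the hand-convolution oracle
  set.seed(16)
  img <- matrix(rnorm(25, 100, 30), 5, 5)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(ceusfuse:::conv2_reflect(img, sx),
               oracle_conv2_reflect(img, sx), tolerance = 1e-12)
  expect_equal(ceusfuse:::conv2_reflect(img, t(sx)),
               oracle_conv2_reflect(img, t(sx)), tolerance = 1e-12)
})

test_that("Laws microstructure features respond to structure, not offsets", {
  expect_true(all(laws_features(matrix(123, 8, 8)) == 0))
  # one-directional stripes excite the L5-paired classes (separable masks
  # need variation in both directions to fire a pure E5E5/R5R5 class);
  # period 4 drives the edge kernel E5, period 2 the ripple kernel R5
  # (period 2 is the Nyquist null of E5)
  stripes4 <- matrix(rep(c(0, 0, 200, 200), length.out = 12), 12, 12)
  expect_gt(laws_features(stripes4)[["laws_L5E5_frequency"]], 0)
  stripes2 <- matrix(rep(c(0, 200), length.out = 12), 12, 12)
  lf2 <- laws_features(stripes2)
  expect_gt(lf2[["laws_L5R5_frequency"]], 0)
  expect_gt(lf2[["laws_L5R5_frequency"]], 10 * lf2[["laws_L5E5_frequency"]])
  # energy maps come from reflected-border convolution (oracle check)
  set.seed(17)
  img <- matrix(rnorm(49), 7, 7)
  v <- ceusfuse:::laws_vectors()
  kern <- outer(v$L5, v$E5)
  expect_equal(ceusfuse:::conv2_reflect(img, kern),
               oracle_conv2_reflect(img, kern), tolerance = 1e-10)
})

test_that("Hurst estimator recovers known roughness regimes", {
  expect_identical(hurst_index(matrix(5, 20, 20)), 0)
  # fractional Brownian surfaces with H = 0.7 (spectral-synthesis oracle)
  set.seed(18)
  est <- vapply(1:20, function(i) hurst_index(oracle_fbm_surface(64, 0.7)), 0)
  expect_lt(abs(mean(est) - 0.7), 0.1)
  # i.i.d. noise is rough: estimate near 0
  noise <- vapply(1:10, function(i)
    hurst_index(matrix(runif(32^2, 0, 255), 32, 32)), 0)
  expect_lt(mean(noise), 0.2)
})

test_that("Haar detail entropies satisfy transform identities", {
  expect_equal(wavelet_entropies(matrix(9, 8, 8)),
               c(wavelet_entropy_l1 = 0, wavelet_entropy_l2 = 0))
  # orthonormal single level on a 2x2 block: hand-computed closed form
  blk <- matrix(c(4, 2, 6, 0), 2, 2)  # a=4 c=2 (col1), b=6 d=0 (col2)
  wt <- ceusfuse:::haar2(blk)
  expect_equal(wt$LL[1, 1], (4 + 6 + 2 + 0) / 2)
  expect_equal(wt$LH[1, 1], (4 - 6 + 2 - 0) / 2)
  expect_equal(wt$HL[1, 1], (4 + 6 - 2 - 0) / 2)
  expect_equal(wt$HH[1, 1], (4 - 6 - 2 + 0) / 2)
  # Parseval: the transform conserves energy
  set.seed(19)
  img <- matrix(rnorm(16 * 16), 16, 16)
  wt <- ceusfuse:::haar2(img)
  expect_equal(sum(unlist(wt)^2), sum(img^2), tolerance = 1e-6)
})

test_that("autocorrelation index matches closed forms and the oracle", {
  expect_identical(autocorrelation_index(matrix(3, 4, 4)), 1)
  checker <- outer(1:10, 1:10, function(r, cc) ifelse((r + cc) %% 2 == 0, 255, 0))
  expect_equal(autocorrelation_index(checker), -1, tolerance = 1e-12)
  set.seed(20)
  x <- matrix(rnorm(20 * 20, 100, 25), 20, 20)
  mu <- mean(x); v <- mean((x - mu)^2)
  ch <- 0; nh <- 0
  for (r in 1:20) for (cc in 1:19) { ch <- ch + (x[r, cc] - mu) * (x[r, cc + 1] - mu); nh <- nh + 1 }
  cv <- 0; nv <- 0
  for (r in 1:19) for (cc in 1:20) { cv <- cv + (x[r, cc] - mu) * (x[r + 1, cc] - mu); nv <- nv + 1 }
  expect_equal(autocorrelation_index(x), mean(c(ch / nh, cv / nv)) / v,
               tolerance = 1e-10)
})

test_that("texture vector is a deterministic 41-feature descriptor", {
  d <- generate_paired_patches(synthetic_params(seed = 23, n_per_class = 1))
  p <- d$bmode[, , 1]
  tv <- texture_vector(p)
  expect_length(tv, 41)
  expect_true(all(is.finite(tv)))
  expect_identical(tv, texture_vector(p))
  expect_length(texture_vector(p[1:16, 1:16]), 41)
  # 90-degree rotation leaves the direction-averaged order-2 Haralick block
  # unchanged (the 45-degree family is closed under quarter turns)
  tv_rot <- texture_vector(ceusfuse:::rot90cw(p))
  expect_equal(tv_rot[1:6], tv[1:6], tolerance = 1e-9)
})

test_that("every feature stays finite on fuzzed 8-bit patches", {
  set.seed(24)
  for (i in 1:40) {
    kind <- i %% 4
    p <- switch(kind + 1,
      matrix(sample(0:255, 18^2, TRUE), 18, 18),
      matrix(sample(0:1, 20^2, TRUE) * 255, 20, 20),
      matrix(sample(100:102, 16^2, TRUE), 16, 16),
      matrix(rep(0:255, length.out = 17^2), 17, 17))
    expect_true(all(is.finite(texture_vector(p))))
  }
})

test_that("feature tables carry per-channel blocks and labels", {
  d <- generate_paired_patches(synthetic_params(seed = 25, n_per_class = 2))
  ft <- texture_features(d, "both")
  feat_cols <- setdiff(colnames(ft), c("label", "frame_id", "augmentation"))
  expect_length(feat_cols, 82)
  expect_true(all(startsWith(feat_cols, "bmode_") | startsWith(feat_cols, "ceus_")))
  expect_identical(ft$label, d$label)
  ft1 <- texture_features(d, "ceus")
  expect_length(setdiff(colnames(ft1), c("label", "frame_id", "augmentation")), 41)
})
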