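test_that("the tiny backbone has the registered tap and output contracts", {
  m <- build_backbone("tiny", seed = 1)
  d <- generate_paired_patches(synthetic_params(seed = 30, n_per_class = 2))
  f <- extract_features(m, d, "bmode")
  expect_identical(dim(f), c(4L, 64L))
  p <- predict_probabilities(m, d, "bmode")
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # feature extraction is pure
  expect_identical(f, extract_features(m, d, "bmode"))
  # all-zero weights give a constant function
  m0 <- m
  for (nm in names(m0$nodes))
    for (par in c("W", "b"))
      if (!is.null(m0$nodes[[nm]][[par]]))
        m0$nodes[[nm]][[par]][] <- 0
  p0 <- predict_probabilities(m0, d, "bmode")
  expect_true(all(abs(p0 - 0.5) < 1e-12))
  # shifting both output logits leaves softmax probabilities unchanged
  m1 <- m
  m1$nodes$fc_out$b <- m1$nodes$fc_out$b + 3.7
  expect_equal(unclass(predict_probabilities(m1, d, "bmode")), unclass(p),
               tolerance = 1e-9)
  expect_error(build_backbone("nope"), "unknown backbone")
  expect_error(build_backbone("tiny", pretrained = TRUE), "pretrained")
})

test_that("the forward pass matches a layer-by-layer manual oracle", {
  # independent re-computation of the tiny network with explicit loops
  m <- build_backbone("tiny", seed = 4)
  set.seed(31)
  img <- matrix(runif(51^2, 0, 255), 51, 51)
  pp <- paired_patches(img, img, "HCC")
  conv_valid <- function(x, W, b, k, cout) {
    h <- nrow(x[[1]]); oh <- h - k + 1
    cin <- length(x)
    out <- vector("list", cout)
    for (co in seq_len(cout)) {
      acc <- matrix(b[co], oh, oh)
      for (ci in seq_len(cin)) for (ki in 1:k) for (kj in 1:k) {
        wrow <- (ci - 1) * k * k + (kj - 1) * k + ki
        acc <- acc + W[wrow, co] *
          x[[ci]][ki:(ki + oh - 1), kj:(kj + oh - 1)]
      }
      out[[co]] <- pmax(acc, 0)
    }
    out
  }
  pool2 <- function(x) lapply(x, function(m_) {
    oh <- floor(nrow(m_) / 2)
    out <- matrix(0, oh, oh)
    for (r in seq_len(oh)) for (cc in seq_len(oh))
      out[r, cc] <- max(m_[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc)])
    out
  })
  x <- list(img / 255 - 0.5)
  x <- conv_valid(x, m$nodes$conv1$W, m$nodes$conv1$b, 5, 8)
  x <- pool2(x)
  x <- conv_valid(x, m$nodes$conv2$W, m$nodes$conv2$b, 3, 16)
  x <- pool2(x)
  x <- conv_valid(x, m$nodes$conv3$W, m$nodes$conv3$b, 3, 64)
  tap_manual <- vapply(x, mean, 0)
  tap_engine <- extract_features(m, pp, "bmode")[1, ]
  expect_equal(tap_engine, tap_manual, tolerance = 1e-10)
  logits <- as.vector(tap_manual %*% m$nodes$fc_out$W + m$nodes$fc_out$b)
  p_manual <- exp(logits) / sum(exp(logits))
  expect_equal(as.vector(predict_probabilities(m, pp, "bmode")[1, ]),
               p_manual, tolerance = 1e-10)
})

test_that("training separates linearly separable patch classes", {
  # bright HCC vs dark PAR constant-ish patches: trivially separable
  set.seed(32)
  n <- 100
  p <- 51
  bm <- array(0, c(p, p, 2 * n))
  for (i in seq_len(2 * n))
    bm[, , i] <- clip8(matrix(rnorm(p^2, if (i <= n) 190 else 70, 12), p, p))
  d <- paired_patches(bm, bm, rep(c("HCC", "PAR"), each = n))
  cfg <- tiny_train_config(seed = 2, epochs = 12)
  m <- train_branch(build_backbone("tiny", seed = 2), d, "bmode", cfg)
  expect_gte(utils::tail(m$history$acc, 1), 0.95)
  # before any update, a random-init model sits at chance-level
  # cross-entropy ln 2 on balanced data
  m_init <- build_backbone("tiny", seed = 2)
  p_init <- predict_probabilities(m_init, d, "bmode")
  y1 <- as.integer(d$label == "HCC")
  ce <- -mean(log(ifelse(y1 == 1, p_init[, 1], p_init[, 2])))
  expect_lt(abs(ce - log(2)), 0.2)
  # seeded training is reproducible
  m2 <- train_branch(build_backbone("tiny", seed = 2), d, "bmode", cfg)
  expect_identical(m$nodes$fc_out$W, m2$nodes$fc_out$W)
  expect_identical(m$history, m2$history)
  expect_error(train_branch(build_backbone("tiny"), d[1:5], "bmode", cfg),
               "both classes")
})

test_that("activation maps reshape tap vectors to the printed sizes", {
  set.seed(33)
  v512 <- rnorm(512)
  am <- activation_map(v512, c(16, 32))
  expect_identical(dim(am), c(16L, 32L))
  expect_equal(range(am), c(0, 255))
  expect_identical(dim(activation_map(rnorm(1920), c(32, 60))), c(32L, 60L))
  # row-major fill: element (1, 2) comes from the second vector entry
  rng <- range(v512)
  expect_equal(am[1, 2], (v512[2] - rng[1]) / diff(rng) * 255,
               tolerance = 1e-12)
  expect_true(all(activation_map(rep(4, 12), c(3, 4)) == 0))
  expect_error(activation_map(rnorm(10), c(3, 4)), "does not match")
})

test_that("the minibatch loss decreases on learnable synthetic data", {
  d <- generate_paired_patches(synthetic_params(seed = 34, n_per_class = 40))
  cfg <- tiny_train_config(seed = 3, epochs = 8)
  m <- train_branch(build_backbone("tiny", seed = 3), d, "ceus", cfg)
  expect_lt(mean(utils::tail(m$history$loss, 2)),
            mean(utils::head(m$history$loss, 2)))
})
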