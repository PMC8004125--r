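# Independent brute-force oracles used across the suite. These are written
# as plainly as possible (explicit loops, no shared code with the package
# internals) so they can serve as references for the vectorized
# implementations.

# point-in-polygon by explicit ray casting for a single point (x, y);
# points exactly on an edge are inside
oracle_point_in_polygon <- function(x, y, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # on-segment test
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cross) < 1e-9 &&
        x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
        y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# order-2 GCM counts by exhaustive double loop; counts pairs at offset
# (dx, dy) and its reflection
oracle_gcm2 <- function(q, dx, dy, n_levels) {
  h <- nrow(q); w <- ncol(q)
  cnt <- matrix(0L, n_levels, n_levels)
  for (r in seq_len(h)) for (cc in seq_len(w)) for (s in c(1L, -1L)) {
    r2 <- r + s * dy; c2 <- cc + s * dx
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w)
      cnt[q[r, cc] + 1L, q[r2, c2] + 1L] <- cnt[q[r, cc] + 1L, q[r2, c2] + 1L] + 1L
  }
  cnt
}

# order-3 GCM counts by exhaustive loop; offsets (d1, d2) and their joint
# reflection
oracle_gcm3 <- function(q, d1, d2, n_levels) {
  h <- nrow(q); w <- ncol(q)
  cnt <- array(0L, rep(n_levels, 3))
  for (r in seq_len(h)) for (cc in seq_len(w)) for (s in c(1L, -1L)) {
    r2 <- r + s * d1[2]; c2 <- cc + s * d1[1]
    r3 <- r + s * d2[2]; c3 <- cc + s * d2[1]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
        r3 >= 1 && r3 <= h && c3 >= 1 && c3 <= w)
      cnt[q[r, cc] + 1L, q[r2, c2] + 1L, q[r3, c3] + 1L] <-
        cnt[q[r, cc] + 1L, q[r2, c2] + 1L, q[r3, c3] + 1L] + 1L
  }
  cnt
}

# Haralick features by naive summation over a dense normalized count array
oracle_haralick <- function(cnt) {
  ord <- length(dim(cnt))
  p <- cnt / sum(cnt)
  idx <- which(p > 0, arr.ind = TRUE) - 1
  pv <- p[p > 0]
  energy <- sum(pv^2)
  entropy <- -sum(pv * log2(pv))
  if (ord == 2) d2 <- (idx[, 1] - idx[, 2])^2
  else d2 <- ((idx[, 1] - idx[, 2])^2 + (idx[, 2] - idx[, 3])^2) / 2
  contrast <- sum(pv * d2)
  homog <- sum(pv / (1 + d2))
  mu <- sapply(seq_len(ord), function(k) sum(pv * idx[, k]))
  va <- sapply(seq_len(ord), function(k) sum(pv * idx[, k]^2) - mu[k]^2)
  pc <- function(i, j) {
    s <- sqrt(va[i] * va[j])
    if (s == 0) 0 else (sum(pv * idx[, i] * idx[, j]) - mu[i] * mu[j]) / s
  }
  corr <- if (ord == 2) pc(1, 2) else mean(c(pc(1, 2), pc(2, 3), pc(1, 3)))
  grand <- mean(mu)
  varf <- sum(pv * rowMeans((idx - grand)^2))
  c(homogeneity = homog, energy = energy, entropy = entropy,
    correlation = corr, contrast = contrast, variance = varf)
}

# 2-D convolution with reflected borders by quadruple loop
oracle_conv2_reflect <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  # symmetric reflection with edge duplication: 0 -> 1, -1 -> 2, n+1 -> n
  refl <- function(i, n) {
    if (i < 1) return(1 - i)
    if (i > n) return(2 * n + 1 - i)
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    acc <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      rr <- refl(r + i - 1 - ry, h)
      cj <- refl(cc + j - 1 - rx, w)
      acc <- acc + kern[i, j] * img[rr, cj]
    }
    out[r, cc] <- acc
  }
  out
}

# fractional Brownian surface with known Hurst exponent via spectral
# synthesis (power spectrum ~ f^-(2H + 2))
oracle_fbm_surface <- function(n, H) {
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fy <- fx
  f2 <- outer(fy^2, fx^2, "+")
  amp <- ifelse(f2 == 0, 0, f2^(-(H + 1) / 2))
  phase <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  spec <- amp * exp(1i * phase)
  surf <- Re(stats::fft(spec, inverse = TRUE)) / n
  surf <- (surf - mean(surf)) / stats::sd(surf)
  surf * 30 + 128
}

# exhaustive CFS search over all non-empty subsets (<= 12 features) using
# precomputed symmetric-uncertainty tables, independent of the package's
# merit code path except for the SU definition
oracle_cfs_exhaustive <- function(xd, y) {
  p <- ncol(xd)
  su <- function(a, b) {
    ent <- function(v) { t <- table(v) / length(v); -sum(t[t > 0] * log2(t[t > 0])) }
    ha <- ent(a); hb <- ent(b)
    if (ha + hb == 0) return(0)
    hab <- ent(paste(a, b))
    2 * (ha + hb - hab) / (ha + hb)
  }
  su_cf <- sapply(seq_len(p), function(j) su(xd[, j], y))
  su_ff <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (i < j) su_ff[i, j] <- su_ff[j, i] <- su(xd[, i], xd[, j])
  best <- NULL; best_m <- -Inf
  for (code in 1:(2^p - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    k <- length(s)
    rcf <- mean(su_cf[s])
    rff <- if (k > 1) mean(su_ff[s, s][upper.tri(diag(k))]) else 0
    m <- k * rcf / sqrt(k + k * (k - 1) * rff)
    if (m > best_m + 1e-12) { best_m <- m; best <- s }
  }
  list(selected = best, merit = best_m)
}

# desk-scale training schedule for the tiny backbone (see vignette)
tiny_train_config <- function(seed = 1L, epochs = 40L)
  train_config(learning_rate = 0.02, momentum = 0.1, minibatch = 25L,
               epochs = epochs, seed = seed)

accuracy_of <- function(p, labels) mean(ifelse(p[, "HCC"] >= 0.5, "HCC", "PAR") == labels)
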