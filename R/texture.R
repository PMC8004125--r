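#' Edge-based texture features
#'
#' Gradients are taken with the 3x3 Sobel operators (reflected borders).
#' Edge pixels are those whose gradient magnitude exceeds the patch mean
#' magnitude. Returns the edge frequency (edge-pixel fraction), edge
#' contrast (mean magnitude over edge pixels) and edge orientation
#' variability (circular variance of the gradient orientation over edge
#' pixels). A patch with no edge pixels (e.g. a constant patch) returns
#' (0, 0, 0).
#'
#' @param patch numeric matrix, at least 3x3.
#' @return named numeric vector
#'   (`edge_frequency`, `edge_contrast`, `edge_orientation_var`).
#' @export
edge_features <- function(patch) {
  stopifnot(nrow(patch) >= 3, ncol(patch) >= 3)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_reflect(patch, sx)
  gy <- conv2_reflect(patch, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  thr <- mean(mag)
  edge <- mag > thr
  if (!any(edge))
    return(c(edge_frequency = 0, edge_contrast = 0, edge_orientation_var = 0))
  theta <- atan2(gy[edge], gx[edge])
  circ_var <- 1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  c(edge_frequency = mean(edge), edge_contrast = mean(mag[edge]),
    edge_orientation_var = circ_var)
}

laws_vectors <- function() {
  list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1), W5 = c(-1, 2, 0, -2, 1),
       R5 = c(1, -4, 6, -4, 1))
}

laws_classes <- function() {
  c("E5E5", "S5S5", "R5R5", "W5W5", "L5E5", "L5S5", "L5R5", "L5W5",
    "E5S5", "E5R5", "E5W5")
}

#' Laws texture-energy features
#'
#' Convolves the patch with 5x5 Laws masks (outer products of the L5, E5,
#' S5, W5, R5 vectors; reflected borders) and forms symmetric-pair energy
#' maps: for an asymmetric class AB the absolute responses of the AB and BA
#' masks are averaged. Eleven zero-sum mask classes are retained
#' (E5E5, S5S5, R5R5, W5W5, L5E5, L5S5, L5R5, L5W5, E5S5, E5R5, E5W5) and
#' per class two microstructure statistics are reported: density (fraction
#' of pixels with energy above the map mean) and frequency (mean energy) --
#' 22 values. A constant patch yields all zeros.
#'
#' @param patch numeric matrix, at least 5x5.
#' @return named numeric vector of 22 features (`laws_<class>_density`,
#'   `laws_<class>_frequency`).
#' @export
laws_features <- function(patch) {
  stopifnot(nrow(patch) >= 5, ncol(patch) >= 5)
  v <- laws_vectors()
  out <- numeric(0)
  for (cls in laws_classes()) {
    a <- substr(cls, 1, 2); b <- substr(cls, 3, 4)
    e1 <- abs(conv2_reflect(patch, outer(v[[a]], v[[b]])))
    emap <- if (a == b) e1 else (e1 + abs(conv2_reflect(patch, outer(v[[b]], v[[a]])))) / 2
    m <- mean(emap)
    density <- if (m > 0) mean(emap > m) else 0
    out <- c(out, density, m)
  }
  names(out) <- as.vector(rbind(paste0("laws_", laws_classes(), "_density"),
                                paste0("laws_", laws_classes(), "_frequency")))
  out
}

#' Hurst fractal index
#'
#' Fractional-Brownian-surface estimator: the slope of
#' `log E|I(p + d) - I(p)|` against `log |d|` over horizontal and vertical
#' lags 1..8, clipped to \[0, 1\]. Rough (noise-like) surfaces give values
#' near 0, smooth persistent surfaces values near 1. A zero-variance patch
#' returns 0 by convention.
#'
#' @param patch numeric matrix, at least 16x16.
#' @return Hurst index in \[0, 1\].
#' @export
hurst_index <- function(patch) {
  stopifnot(nrow(patch) >= 16, ncol(patch) >= 16)
  if (stats::sd(patch) == 0) return(0)
  lags <- 1:8
  md <- vapply(lags, function(g) {
    h <- nrow(patch); w <- ncol(patch)
    dh <- abs(patch[, (g + 1):w, drop = FALSE] - patch[, 1:(w - g), drop = FALSE])
    dv <- abs(patch[(g + 1):h, , drop = FALSE] - patch[1:(h - g), , drop = FALSE])
    mean(c(dh, dv))
  }, 0)
  if (any(md <= 0)) return(0)
  h_est <- stats::coef(stats::lm(log(md) ~ log(lags)))[[2]]
  min(max(h_est, 0), 1)
}

haar2 <- function(m) {
  # one orthonormal 2-D Haar level; odd trailing row/col cropped
  h <- nrow(m) %/% 2L * 2L; w <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  a <- m[seq(1, h, 2), seq(1, w, 2), drop = FALSE]
  b <- m[seq(1, h, 2), seq(2, w, 2), drop = FALSE]
  c <- m[seq(2, h, 2), seq(1, w, 2), drop = FALSE]
  d <- m[seq(2, h, 2), seq(2, w, 2), drop = FALSE]
  list(LL = (a + b + c + d) / 2, LH = (a - b + c - d) / 2,
       HL = (a + b - c - d) / 2, HH = (a - b - c + d) / 2)
}

#' Wavelet detail entropies
#'
#' Applies the orthonormal 2-D Haar transform recursively twice and reports,
#' per level, the Shannon entropy (base 2, `0 log 0 = 0`) of the
#' energy-normalized detail coefficients, the three detail subbands pooled.
#' Levels with zero detail energy (e.g. a constant patch) contribute 0.
#'
#' @param patch numeric matrix, at least 4x4.
#' @return named numeric vector (`wavelet_entropy_l1`, `wavelet_entropy_l2`).
#' @export
wavelet_entropies <- function(patch) {
  stopifnot(nrow(patch) >= 4, ncol(patch) >= 4)
  out <- numeric(2)
  m <- patch
  for (lev in 1:2) {
    wt <- haar2(m)
    det2 <- c(wt$LH, wt$HL, wt$HH)^2
    tot <- sum(det2)
    if (tot > 0) {
      p <- det2[det2 > 0] / tot
      out[lev] <- -sum(p * log2(p))
    }
    m <- wt$LL
  }
  names(out) <- c("wavelet_entropy_l1", "wavelet_entropy_l2")
  out
}

#' First-lag autocorrelation index
#'
#' Mean of the normalized autocorrelation (covariance at lag divided by the
#' patch variance, using the global patch mean) at lags (1, 0) and (0, 1).
#' Measures granularity: fine speckle decorrelates quickly, coarse texture
#' stays correlated. A constant patch returns 1 by convention.
#'
#' @param patch numeric matrix, at least 2x2.
#' @return scalar autocorrelation index.
#' @export
autocorrelation_index <- function(patch) {
  stopifnot(nrow(patch) >= 2, ncol(patch) >= 2)
  mu <- mean(patch)
  v <- mean((patch - mu)^2)
  if (v == 0) return(1)
  h <- nrow(patch); w <- ncol(patch)
  ch <- mean((patch[, 1:(w - 1)] - mu) * (patch[, 2:w] - mu))
  cv <- mean((patch[1:(h - 1), ] - mu) * (patch[2:h, ] - mu))
  mean(c(ch, cv)) / v
}

#' The 41-feature texture vector
#'
#' The complete per-channel texture descriptor used by the conventional
#' baseline: 6 Haralick features on the direction-averaged order-2
#' co-occurrence matrix (256 gray levels, 8 unit displacements at 45-degree
#' multiples), 6 Haralick features on the order-3 generalized co-occurrence
#' matrix (64 gray levels, 4 collinear + 4 right-angle configurations),
#' 3 edge features, the autocorrelation index, the Hurst index, 2 wavelet
#' detail entropies, and 22 Laws microstructure statistics -- 41 named
#' values. Haralick features are computed per spatial configuration and
#' arithmetically averaged across the family. For two-channel experiments
#' the per-channel vectors are concatenated downstream (82 features; see
#' [texture_features()]).
#'
#' @param patch numeric matrix of 8-bit gray levels, at least 16x16.
#' @param n_levels2,n_levels3 quantization levels of the order-2 and order-3
#'   co-occurrence matrices (defaults 256 and 64).
#' @return named numeric vector of length 41.
#' @export
texture_vector <- function(patch, n_levels2 = 256L, n_levels3 = 64L) {
  stopifnot(is.matrix(patch), nrow(patch) >= 16, ncol(patch) >= 16)
  cfg2 <- gcm_config(2L, n_levels2)
  cfg3 <- gcm_config(3L, n_levels3)
  h2 <- haralick_mean(quantize(patch, n_levels2), cfg2)
  h3 <- haralick_mean(quantize(patch, n_levels3), cfg3)
  names(h2) <- paste0("gcm2_", names(h2))
  names(h3) <- paste0("gcm3_", names(h3))
  out <- c(h2, h3, edge_features(patch),
           autocorrelation = autocorrelation_index(patch),
           hurst = hurst_index(patch),
           wavelet_entropies(patch), laws_features(patch))
  stopifnot(length(out) == 41L)
  out
}

#' Texture feature table of a patch collection
#'
#' Computes [texture_vector()] per patch on the requested channel(s) and
#' returns a data frame with one row per patch, the feature columns
#' (prefixed `bmode_` / `ceus_` for `channels = "both"`, 82 columns), a
#' `label` column, and provenance columns when available.
#'
#' @param patches a [paired_patches()] collection.
#' @param channels `"bmode"`, `"ceus"`, or `"both"`.
#' @return a data frame.
#' @export
texture_features <- function(patches, channels = c("bmode", "ceus", "both")) {
  channels <- match.arg(channels)
  stopifnot(inherits(patches, "paired_patches"))
  n <- length(patches)
  chans <- if (channels == "both") c("bmode", "ceus") else channels
  mats <- list()
  for (ch in chans) {
    m <- t(vapply(seq_len(n),
                  function(i) texture_vector(patches[[ch]][, , i]),
                  numeric(41)))
    if (channels == "both") colnames(m) <- paste0(ch, "_", colnames(m))
    mats[[ch]] <- m
  }
  out <- data.frame(do.call(cbind, mats), check.names = FALSE)
  out$label <- patches$label
  if (!is.null(patches$origin)) {
    out$frame_id <- patches$origin$frame_id
    out$augmentation <- patches$augmentation
  }
  out
}
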