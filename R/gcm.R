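#' Uniform gray-level quantization
#'
#' Bins the 8-bit range \[0, 255\] uniformly into `n_levels` levels:
#' `value -> floor(value * n_levels / 256)`.
#'
#' @param patch numeric matrix of 8-bit gray levels.
#' @param n_levels number of quantized levels, in \[2, 256\].
#' @return integer matrix with values in `0 .. n_levels - 1`.
#' @export
quantize <- function(patch, n_levels) {
  if (!is_count(n_levels) || n_levels < 2 || n_levels > 256)
    stopf("n_levels must be an integer in [2, 256]")
  q <- floor(patch * n_levels / 256)
  q[q > n_levels - 1] <- n_levels - 1
  q[q < 0] <- 0
  storage.mode(q) <- "integer"
  q
}

#' Generalized co-occurrence matrix configuration
#'
#' Defines the spatial configuration family of a generalized co-occurrence
#' matrix (GCM). An order-2 configuration is one displacement vector
#' `(dx, dy)` (x = column, y = row, y downward); an order-3 configuration is
#' a pair of displacements from the current pixel. The default order-2 family
#' is the 8 unit displacements at 45-degree multiples; the default order-3
#' family is 4 collinear orientations (0, 45, 90, 135 degrees, current pixel
#' central) plus 4 right-angle configurations with the current pixel at the
#' vertex. For every configuration, tuples are counted for the displacement
#' set and for its point reflection (both signs), so each count matrix is
#' symmetric under reversal of the pixel tuple.
#'
#' @param order 2 or 3.
#' @param n_levels quantized gray levels; defaults: 256 for order 2, 64 for
#'   order 3 (the order-3 cube is accumulated sparsely).
#' @param displacements optional list of configurations; each configuration
#'   is a list of `order - 1` integer `c(dx, dy)` vectors.
#' @return an object of class `gcm_config`.
#' @export
gcm_config <- function(order = 2L, n_levels = if (order == 2) 256L else 64L,
                       displacements = NULL) {
  if (!order %in% c(2L, 3L)) stopf("order must be 2 or 3")
  if (is.null(displacements)) {
    if (order == 2) {
      dirs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L),
                   c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
      displacements <- lapply(dirs, list)
    } else {
      col <- lapply(list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L)),
                    function(u) list(u, -u))
      ra <- list(list(c(1L, 0L), c(0L, 1L)),
                 list(c(0L, 1L), c(-1L, 0L)),
                 list(c(-1L, 0L), c(0L, -1L)),
                 list(c(0L, -1L), c(1L, 0L)))
      displacements <- c(col, ra)
    }
  }
  for (cfg in displacements) {
    if (length(cfg) != order - 1L)
      stopf("order-%d configurations need %d displacement(s)", order, order - 1L)
    for (d in cfg)
      if (length(d) != 2 || all(d == 0))
        stopf("each displacement needs a nonzero (dx, dy)")
  }
  structure(list(order = as.integer(order), n_levels = as.integer(n_levels),
                 displacements = displacements),
            class = "gcm_config")
}

# count tuples for one configuration (list of order-1 offsets), both signs
count_config <- function(q, cfg, n_levels) {
  h <- nrow(q); w <- ncol(q)
  keys <- integer(0)
  for (sgn in c(1L, -1L)) {
    offs <- lapply(cfg, function(d) sgn * d)
    dys <- vapply(offs, `[`, 0L, 2L); dxs <- vapply(offs, `[`, 0L, 1L)
    r0 <- max(1L, 1L - min(0L, dys)); r1 <- min(h, h - max(0L, dys))
    c0 <- max(1L, 1L - min(0L, dxs)); c1 <- min(w, w - max(0L, dxs))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    k <- as.integer(q[rows, cols])
    for (j in seq_along(offs))
      k <- k * n_levels + as.integer(q[rows + dys[j], cols + dxs[j]])
    keys <- c(keys, k)
  }
  keys
}

#' Compute a generalized co-occurrence matrix
#'
#' Accumulates counts of pixel tuples in the spatial configurations of
#' `config` over a quantized patch, summed over the whole configuration
#' family; tuples extending beyond the patch are skipped. A patch smaller
#' than the displacement extent yields an empty GCM (total 0), not an error.
#'
#' @param patch integer matrix of quantized levels in `0 .. n_levels - 1`
#'   (see [quantize()]).
#' @param config a [gcm_config()].
#' @return an object of class `gcm`: sparse cell table (`cells`: columns
#'   `f1..fn`, `count`), `total`, and `config`.
#' @export
compute_gcm <- function(patch, config) {
  stopifnot(inherits(config, "gcm_config"))
  if (max(patch) > config$n_levels - 1 || min(patch) < 0)
    stopf("patch values must be quantized to 0..%d (see quantize())",
          config$n_levels - 1)
  keys <- integer(0)
  for (cfg in config$displacements)
    keys <- c(keys, count_config(patch, cfg, config$n_levels))
  gcm_from_keys(keys, config)
}

gcm_from_keys <- function(keys, config) {
  n <- config$n_levels; ord <- config$order
  if (length(keys)) {
    bins <- tabulate(keys + 1L, nbins = n^ord)
    key <- which(bins > 0) - 1L
    cnt <- bins[key + 1L]
  } else {
    key <- numeric(0); cnt <- integer(0)
  }
  cells <- matrix(0L, length(key), ord)
  k <- key
  for (j in ord:1) {
    cells[, j] <- as.integer(k %% n)
    k <- k %/% n
  }
  colnames(cells) <- paste0("f", seq_len(ord))
  structure(list(cells = cells, count = cnt, total = sum(cnt),
                 config = config), class = "gcm")
}

#' @export
print.gcm <- function(x, ...) {
  cat(sprintf("<gcm> order %d, %d levels, %d occupied cell(s), total %d\n",
              x$config$order, x$config$n_levels, nrow(x$cells), x$total))
  invisible(x)
}

#' Dense count array of a GCM
#'
#' @param gcm a [compute_gcm()] result.
#' @return an `n_levels^order` array of counts.
#' @export
gcm_counts <- function(gcm) {
  n <- gcm$config$n_levels; ord <- gcm$config$order
  a <- array(0L, rep(n, ord))
  if (nrow(gcm$cells)) a[gcm$cells + 1L] <- gcm$count
  a
}

#' Haralick features of a co-occurrence matrix
#'
#' Six statistics of the probability-normalized GCM: energy, entropy
#' (base 2), contrast, local homogeneity, correlation, and variance. For
#' order 3 the pairwise generalizations are used: contrast
#' `sum p ((f1-f2)^2 + (f2-f3)^2) / 2`, local homogeneity
#' `sum p / (1 + ((f1-f2)^2 + (f2-f3)^2)/2)`, correlation = mean of the three
#' two-index correlations, and variance `sum p * mean_i (f_i - mu)^2` with
#' `mu` the grand mean of the index marginals. When a marginal standard
#' deviation is zero the corresponding correlation term is 0 by convention.
#'
#' @param gcm a [compute_gcm()] result with `total > 0`.
#' @return named numeric vector of 6 features
#'   (`homogeneity`, `energy`, `entropy`, `correlation`, `contrast`,
#'   `variance`).
#' @export
haralick <- function(gcm) {
  stopifnot(inherits(gcm, "gcm"))
  if (gcm$total <= 0) stopf("empty GCM: no tuples counted")
  p <- gcm$count / gcm$total
  f <- gcm$cells
  ord <- gcm$config$order
  energy <- sum(p^2)
  entropy <- -sum(p * log2(p))
  if (ord == 2) {
    d2 <- (f[, 1] - f[, 2])^2
  } else {
    d2 <- ((f[, 1] - f[, 2])^2 + (f[, 2] - f[, 3])^2) / 2
  }
  contrast <- sum(p * d2)
  homogeneity <- sum(p / (1 + d2))
  mu <- colSums(p * f)
  va <- colSums(p * f^2) - mu^2
  pair_cor <- function(i, j) {
    s <- sqrt(va[i] * va[j])
    if (s == 0) return(0)
    unname((sum(p * f[, i] * f[, j]) - mu[i] * mu[j]) / s)
  }
  correlation <- if (ord == 2) pair_cor(1, 2) else
    mean(c(pair_cor(1, 2), pair_cor(2, 3), pair_cor(1, 3)))
  grand <- mean(mu)
  variance <- sum(p * rowMeans((f - matrix(grand, nrow(f), ord))^2))
  c(homogeneity = homogeneity, energy = energy, entropy = entropy,
    correlation = correlation, contrast = contrast, variance = variance)
}

# mean of per-configuration Haralick features over the family of `config`
haralick_mean <- function(qpatch, config) {
  feats <- NULL
  for (cfg in config$displacements) {
    keys <- count_config(qpatch, cfg, config$n_levels)
    g <- gcm_from_keys(keys, gcm_config(config$order, config$n_levels,
                                        displacements = list(cfg)))
    if (g$total == 0) next
    feats <- rbind(feats, haralick(g))
  }
  if (is.null(feats)) stopf("patch smaller than every displacement extent")
  colMeans(feats)
}
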