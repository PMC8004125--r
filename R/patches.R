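#' Rasterize a polygon over a pixel grid
#'
#' Even-odd ray-casting test applied to every pixel center. Matrix element
#' `[r, c]` corresponds to the 0-based pixel coordinate `(x, y) = (c-1, r-1)`
#' (x = column, y = row, origin at the top-left, the VIA convention). Pixel
#' centers lying exactly on a polygon edge count as inside (deterministic tie
#' rule).
#'
#' @param vertices `n x 2` matrix of (x, y) polygon vertices, `n >= 3`.
#' @param h,w grid dimensions in pixels.
#' @param offset length-2 integer (x0, y0): the grid's top-left pixel sits at
#'   0-based frame coordinate (x0, y0). Default `c(0, 0)`.
#' @return an `h x w` logical matrix.
#' @export
polygon_mask <- function(vertices, h, w, offset = c(0, 0)) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  px <- rep(seq_len(w) - 1 + offset[1], each = h)
  py <- rep(seq_len(h) - 1 + offset[2], times = w)
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  inside <- rep(FALSE, h * w)
  on_edge <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary test: point collinear with segment and within its bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_edge <- on_edge | (abs(cross) < 1e-9 &
                            px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
                            py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9)
    j <- i
  }
  matrix(inside | on_edge, h, w)
}

polygon_area <- function(v) {
  n <- nrow(v); j <- c(n, seq_len(n - 1))
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Extract labeled paired patches around an annotated tumor
#'
#' Implements the strict inside/outside labeling rule: the polygon centroid is
#' located, a `region x region` search window is centered on it, and the
#' window is tiled by non-overlapping `patch_size x patch_size` candidates
#' (stride = `patch_size`, anchored at the window's top-left corner). For each
#' candidate the intersection with the polygon is the number of its pixel
#' centers classified inside. A candidate whose intersection equals
#' `patch_size^2` (2601 for the default 51-pixel patch) is labeled `HCC`; one
#' whose intersection is 0 is labeled `PAR`; anything in between is discarded.
#' The window is clipped to the frame and only fully in-bounds candidates are
#' kept.
#'
#' @param image_pair list with `bmode` and `ceus` matrices of equal size.
#' @param polygon `n x 2` matrix of 0-based (x, y) vertices (or an annotation
#'   list with a `vertices` element).
#' @param patch_size patch side in pixels (default 51).
#' @param region search window side in pixels (default 250).
#' @param frame_id provenance identifier stored with each patch.
#' @return a [paired_patches()] collection (possibly empty) with `origin`
#'   rows giving the 0-based top-left corner of each patch, and an attribute
#'   `"intersection"` holding the pixel intersection of every emitted patch.
#' @export
extract_patches <- function(image_pair, polygon, patch_size = 51L,
                            region = 250L, frame_id = "frame") {
  if (is.list(polygon) && !is.null(polygon$vertices)) {
    if (!is.null(polygon$frame_id)) frame_id <- polygon$frame_id
    polygon <- polygon$vertices
  }
  stopifnot(is.matrix(polygon), nrow(polygon) >= 3)
  if (polygon_area(polygon) <= 0) stopf("degenerate polygon with zero area")
  bm <- image_pair$bmode; ce <- image_pair$ceus
  if (!identical(dim(bm), dim(ce))) stopf("bmode/ceus frame dimensions differ")
  h <- nrow(bm); w <- ncol(bm)
  # polygon center = arithmetic centroid of the vertices, nearest pixel
  cx <- round(mean(polygon[, 1])); cy <- round(mean(polygon[, 2]))
  x0 <- cx - floor(region / 2); y0 <- cy - floor(region / 2)  # 0-based corner
  x0 <- max(0, min(x0, w - region)); y0 <- max(0, min(y0, h - region))
  if (w < region) x0 <- 0
  if (h < region) y0 <- 0
  k <- floor(region / patch_size)
  anchors_x <- x0 + (seq_len(k) - 1L) * patch_size
  anchors_y <- y0 + (seq_len(k) - 1L) * patch_size
  keep_b <- list(); keep_c <- list(); lab <- character(0)
  org <- list(); inter <- integer(0)
  full <- patch_size^2
  for (ay in anchors_y) for (ax in anchors_x) {
    if (ax < 0 || ay < 0 || ax + patch_size > w || ay + patch_size > h) next
    m <- polygon_mask(polygon, patch_size, patch_size, offset = c(ax, ay))
    s <- sum(m)
    if (s != 0L && s != full) next
    rows <- ay + seq_len(patch_size); cols <- ax + seq_len(patch_size)
    keep_b[[length(keep_b) + 1L]] <- bm[rows, cols]
    keep_c[[length(keep_c) + 1L]] <- ce[rows, cols]
    lab <- c(lab, if (s == full) "HCC" else "PAR")
    inter <- c(inter, s)
    org[[length(org) + 1L]] <- data.frame(frame_id = frame_id, row = ay,
                                          col = ax, stringsAsFactors = FALSE)
  }
  if (!length(lab)) {
    out <- paired_patches(array(0, c(patch_size, patch_size, 0)),
                          array(0, c(patch_size, patch_size, 0)),
                          character(0),
                          data.frame(frame_id = character(0), row = integer(0),
                                     col = integer(0)))
  } else {
    out <- paired_patches(
      array(unlist(keep_b), c(patch_size, patch_size, length(lab))),
      array(unlist(keep_c), c(patch_size, patch_size, length(lab))),
      lab, do.call(rbind, org))
  }
  attr(out, "intersection") <- inter
  out
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Rotation augmentation
#'
#' Expands a patch collection with its 90, 180 and 270 degree rotations
#' (output size = 4x input). Both channels are rotated identically and labels
#' are preserved.
#'
#' @param patches a [paired_patches()] collection of square patches.
#' @return a [paired_patches()] collection, originals first, then the three
#'   rotated copies, with augmentation tags `rot90`/`rot180`/`rot270`.
#' @export
augment_rotations <- function(patches) {
  stopifnot(inherits(patches, "paired_patches"))
  p <- dim(patches$bmode)[1]
  if (p != dim(patches$bmode)[2]) stopf("rotation augmentation needs square patches")
  n <- length(patches)
  rot_all <- function(a, times) {
    out <- array(0, dim(a))
    for (i in seq_len(dim(a)[3])) {
      m <- a[, , i]
      for (t in seq_len(times)) m <- rot90cw(m)
      out[, , i] <- m
    }
    out
  }
  pieces <- list(patches)
  for (t in 1:3) {
    pieces[[t + 1L]] <- paired_patches(rot_all(patches$bmode, t),
                                       rot_all(patches$ceus, t),
                                       patches$label, patches$origin,
                                       rep(sprintf("rot%d", 90 * t), n))
  }
  do.call(c, pieces)
}

translate_reflect <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  idx_r <- seq_len(h) - dr; idx_c <- seq_len(w) - dc
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  m[reflect(idx_r, h), reflect(idx_c, w), drop = FALSE]
}

#' Train-time random flip/translation augmentation
#'
#' Randomly applies a horizontal flip, a vertical flip, and an integer
#' translation of up to `max_shift` pixels with reflected padding --
#' identically to both channels of every pair. Labels are unchanged. The draw
#' is taken from the current RNG state, so it is reproducible under
#' `set.seed()`.
#'
#' @param patches a [paired_patches()] collection.
#' @param max_shift maximum absolute translation per axis (default 5).
#' @return an augmented [paired_patches()] collection of the same length.
#' @export
train_time_augment <- function(patches, max_shift = 5L) {
  stopifnot(inherits(patches, "paired_patches"))
  n <- length(patches)
  bm <- patches$bmode; ce <- patches$ceus
  tags <- patches$augmentation
  for (i in seq_len(n)) {
    fh <- stats::runif(1) < 0.5
    fv <- stats::runif(1) < 0.5
    dr <- sample(-max_shift:max_shift, 1L)
    dc <- sample(-max_shift:max_shift, 1L)
    op <- function(m) {
      if (fh) m <- m[, ncol(m):1, drop = FALSE]
      if (fv) m <- m[nrow(m):1, , drop = FALSE]
      if (dr != 0 || dc != 0) m <- translate_reflect(m, dr, dc)
      m
    }
    bm[, , i] <- op(bm[, , i]); ce[, , i] <- op(ce[, , i])
    if (fh || fv || dr != 0 || dc != 0)
      tags[i] <- paste(c(if (fh) "flip_h", if (fv) "flip_v",
                         if (dr != 0 || dc != 0) "translate"), collapse = "+")
  }
  out <- paired_patches(bm, ce, patches$label, patches$origin, tags)
  # pixelwise fusion commutes with flips/translations: re-fuse the channels
  if (!is.null(patches$fuse_spec))
    out <- fuse_patches(out, patches$fuse_spec$method, patches$fuse_spec$weights)
  out
}
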