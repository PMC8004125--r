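#' @keywords internal
"_PACKAGE"

# Clip to the 8-bit gray range and round. All image-level outputs in the
# package go through this so every stored patch/frame is a valid 8-bit image.
clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Bilinear image resize
#'
#' Resizes a 2-D numeric matrix to a target size by bilinear interpolation,
#' sampling at pixel centers. Used to adapt 51x51 ultrasound patches to the
#' native input sizes of the standard CNN backbones (224 or 227 pixels).
#'
#' @param img numeric matrix.
#' @param out_h,out_w target dimensions in pixels.
#' @return an `out_h` x `out_w` numeric matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # map output pixel centers into input coordinates (align pixel centers)
  ry <- if (out_h == 1) rep(1, out_h) else (seq_len(out_h) - 0.5) * h / out_h + 0.5
  rx <- if (out_w == 1) rep(1, out_w) else (seq_len(out_w) - 0.5) * w / out_w + 0.5
  ry <- pmin(pmax(ry, 1), h); rx <- pmin(pmax(rx, 1), w)
  y0 <- pmin(floor(ry), h - 1L); x0 <- pmin(floor(rx), w - 1L)
  if (h == 1) y0 <- rep(1, out_h)
  if (w == 1) x0 <- rep(1, out_w)
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c * wy * (1 - wx) + d * wy * wx
}

# 2-D convolution (correlation) with reflected borders, 'same' output size.
# kern is a (2r+1)x(2r+1) matrix. Used by Laws maps and Sobel gradients.
conv2_reflect <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  # reflect padding (edge pixels not duplicated: 2,1|1,2 style "reflect 101"
  # is avoided; we use simple mirror with edge duplication, scipy 'reflect')
  iy <- c(rev(seq_len(ry)), seq_len(h), h + 1L - seq_len(ry))
  ix <- c(rev(seq_len(rx)), seq_len(w), w + 1L - seq_len(rx))
  pad <- img[iy, ix, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w), drop = FALSE]
    }
  }
  out
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
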