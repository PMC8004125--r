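#' Parameters of the synthetic paired-modality generator
#'
#' The generator emulates the statistical structure the classification
#' pipeline assumes about its two tissue classes. HCC (hepatocellular
#' carcinoma) patches are heterogeneous -- a smoothed Gaussian random field
#' with a larger marginal spread and coarser correlation structure, with an
#' optional dark "necrosis" blob population -- and are hyper-enhanced in the
#' CEUS channel through an additive arterial-phase enhancement offset. PAR
#' (cirrhotic parenchyma) patches are comparatively homogeneous fine-grained
#' fields. The two channels of a pair share a correlated random field
#' (`cross_channel_rho`) and each receives an independent per-patch
#' multiplicative gain jitter (`gain_sd`), the synthetic counterpart of
#' between-acquisition gain/TGC variation; it is what keeps the two classes
#' overlapping enough that single-modality classifiers stay imperfect and
#' fusion has headroom.
#'
#' @param seed integer seed; the generator is fully reproducible given it.
#' @param n_per_class patches to draw per class.
#' @param patch_size patch side in pixels (default 51).
#' @param bmode_mean named vector `c(HCC=, PAR=)` of B-mode class mean gray
#'   levels in \[0, 255\].
#' @param ceus_enhancement_offset gray-level offset added to the HCC CEUS
#'   channel (arterial-phase hyper-enhancement).
#' @param correlation_length named vector `c(HCC=, PAR=)`, Gaussian smoothing
#'   bandwidth of the random field in pixels (> 0).
#' @param field_sd named vector `c(HCC=, PAR=)`, marginal standard deviation
#'   of the random field in gray levels.
#' @param necrosis_fraction probability in \[0, 1\] that an HCC pair receives
#'   a dark necrosis blob population (2--4 disks, radius ~ U(3, 8) px, 60 gray
#'   levels below the class mean, applied to both channels).
#' @param cross_channel_rho correlation in \[-1, 1\] between the B-mode and
#'   CEUS random fields of a pair.
#' @param gain_sd named vector `c(bmode=, ceus=)`, standard deviation of the
#'   per-patch multiplicative gain (gain = 1 + N(0, gain_sd), drawn
#'   independently per channel and per patch).
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(seed = 1L,
                             n_per_class = 100L,
                             patch_size = 51L,
                             bmode_mean = c(HCC = 130, PAR = 100),
                             ceus_enhancement_offset = 25,
                             correlation_length = c(HCC = 3.5, PAR = 1.8),
                             field_sd = c(HCC = 20, PAR = 12),
                             necrosis_fraction = 0.3,
                             cross_channel_rho = 0.6,
                             gain_sd = c(bmode = 0.13, ceus = 0.15)) {
  if (!is_count(n_per_class)) stopf("n_per_class must be a positive integer")
  if (!is_count(patch_size) || patch_size < 4) stopf("patch_size must be >= 4")
  for (nm in c("HCC", "PAR")) {
    if (!nm %in% names(bmode_mean)) stopf("bmode_mean needs an '%s' entry", nm)
    if (!nm %in% names(correlation_length)) stopf("correlation_length needs '%s'", nm)
    if (!nm %in% names(field_sd)) stopf("field_sd needs '%s'", nm)
  }
  if (any(bmode_mean < 0 | bmode_mean > 255)) stopf("bmode_mean must lie in [0,255]")
  if (any(correlation_length <= 0)) stopf("correlation_length must be > 0")
  if (any(field_sd < 0)) stopf("field_sd must be >= 0")
  if (necrosis_fraction < 0 || necrosis_fraction > 1)
    stopf("necrosis_fraction must lie in [0,1]")
  if (abs(cross_channel_rho) > 1) stopf("cross_channel_rho must lie in [-1,1]")
  if (any(gain_sd < 0)) stopf("gain_sd must be >= 0")
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 patch_size = as.integer(patch_size), bmode_mean = bmode_mean,
                 ceus_enhancement_offset = ceus_enhancement_offset,
                 correlation_length = correlation_length, field_sd = field_sd,
                 necrosis_fraction = necrosis_fraction,
                 cross_channel_rho = cross_channel_rho, gain_sd = gain_sd),
            class = "synthetic_params")
}

# Smoothed unit-variance Gaussian random field: white noise convolved with a
# separable Gaussian kernel of bandwidth cl, kernel L2-normalized so that the
# marginal variance stays 1 (no per-patch restandardization -- sample spread
# keeps its natural variability).
gaussian_field <- function(h, w, cl) {
  t <- max(1L, ceiling(3 * cl))
  g <- stats::dnorm(seq(-t, t), sd = cl)
  g <- g / sqrt(sum(g^2))
  noise <- matrix(stats::rnorm((h + 2 * t) * (w + 2 * t)), h + 2 * t, w + 2 * t)
  # separable valid convolution via banded matrices
  Kh <- matrix(0, h, h + 2 * t)
  for (i in seq_len(h)) Kh[i, i:(i + 2 * t)] <- g
  Kw <- matrix(0, w, w + 2 * t)
  for (i in seq_len(w)) Kw[i, i:(i + 2 * t)] <- g
  Kh %*% noise %*% t(Kw)
}

# union mask of nb disks with radius ~ U(rmin, rmax), centers uniform
necrosis_mask <- function(p) {
  nb <- sample(2:4, 1L)
  mask <- matrix(FALSE, p, p)
  rr <- row(mask); cc <- col(mask)
  for (b in seq_len(nb)) {
    r <- stats::runif(1, 3, 8)
    cy <- stats::runif(1, 1, p); cx <- stats::runif(1, 1, p)
    mask <- mask | ((rr - cy)^2 + (cc - cx)^2 <= r^2)
  }
  mask
}

# one pair of correlated class fields -> clipped 8-bit patch pair
draw_pair <- function(params, class) {
  p <- params$patch_size
  cl <- params$correlation_length[[class]]
  sdv <- params$field_sd[[class]]
  rho <- params$cross_channel_rho
  fb <- gaussian_field(p, p, cl)
  fc <- rho * fb + sqrt(1 - rho^2) * gaussian_field(p, p, cl)
  base_b <- params$bmode_mean[[class]] + sdv * fb
  base_c <- params$bmode_mean[[class]] + sdv * fc
  if (class == "HCC") {
    base_c <- base_c + params$ceus_enhancement_offset
    if (stats::runif(1) < params$necrosis_fraction) {
      nm <- necrosis_mask(p)
      base_b <- base_b - 60 * nm
      base_c <- base_c - 60 * nm
    }
  }
  gb <- 1 + stats::rnorm(1, 0, params$gain_sd[["bmode"]])
  gc_ <- 1 + stats::rnorm(1, 0, params$gain_sd[["ceus"]])
  list(bmode = clip8(gb * base_b), ceus = clip8(gc_ * base_c))
}

#' Generate labeled paired patches
#'
#' Draws `n_per_class` synthetic B-mode/CEUS patch pairs per class from the
#' generative model described in [synthetic_params()]. Output is bitwise
#' reproducible given `params$seed`.
#'
#' @param params a [synthetic_params()] object.
#' @return a [paired_patches()] collection of `2 * n_per_class` pairs
#'   (HCC first, then PAR).
#' @examples
#' pp <- generate_paired_patches(synthetic_params(seed = 7, n_per_class = 3))
#' table(pp$label)
#' @export
generate_paired_patches <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params$patch_size; n <- params$n_per_class
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  bm <- array(0, c(p, p, 2L * n)); ce <- array(0, c(p, p, 2L * n))
  lab <- rep(c("HCC", "PAR"), each = n)
  for (i in seq_len(2L * n)) {
    pr <- draw_pair(params, lab[i])
    bm[, , i] <- pr$bmode; ce[, , i] <- pr$ceus
  }
  paired_patches(bm, ce, lab,
                 origin = data.frame(frame_id = "synthetic",
                                     row = NA_integer_, col = NA_integer_,
                                     stringsAsFactors = FALSE)[rep(1, 2L * n), ])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic annotated study
#'
#' Builds whole co-registered B-mode/CEUS frames in which a blob-shaped
#' HCC-textured region sits on a PAR-textured background, together with the
#' delineating polygon of each frame -- a fixture for the patch-extraction
#' workflow on annotated images.
#'
#' @param params a [synthetic_params()] object (class texture parameters).
#' @param frame_size integer vector (height, width); both must be at least
#'   `250 + patch_size` so a full search region fits around the tumor.
#' @param n_frames number of frame pairs.
#' @param seed integer seed.
#' @return an object of class `annotated_study`: list with `frames` (each a
#'   list with `bmode` and `ceus` matrices), `polygons` (each an `n x 2`
#'   matrix of 0-based (x, y) vertex coordinates, x = column, y = row),
#'   and `patient_id`.
#' @export
generate_annotated_study <- function(params, frame_size = c(360, 360),
                                     n_frames = 1L, seed = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  if (length(frame_size) == 1L) frame_size <- rep(frame_size, 2L)
  need <- 250L + params$patch_size
  if (any(frame_size < need))
    stopf("frame_size must be at least %d in both dimensions", need)
  if (!is_count(n_frames)) stopf("n_frames must be a positive integer")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h <- frame_size[1]; w <- frame_size[2]
  frames <- vector("list", n_frames); polys <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    # star-shaped tumor polygon around the frame center
    nv <- 12L
    cy <- h / 2 + stats::runif(1, -10, 10)
    cx <- w / 2 + stats::runif(1, -10, 10)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(1, 80, 110) * stats::runif(nv, 0.75, 1.25)
    rad <- pmin(rad, min(cy, cx, h - cy, w - cx) - 2)
    vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
    poly <- cbind(x = vx - 1, y = vy - 1)   # 0-based pixel coordinates
    mask <- polygon_mask(poly, h, w)
    tex <- list()
    for (class in c("PAR", "HCC")) {
      cl <- params$correlation_length[[class]]; sdv <- params$field_sd[[class]]
      fb <- gaussian_field(h, w, cl)
      fc <- params$cross_channel_rho * fb +
        sqrt(1 - params$cross_channel_rho^2) * gaussian_field(h, w, cl)
      mb <- params$bmode_mean[[class]] + sdv * fb
      mc <- params$bmode_mean[[class]] + sdv * fc +
        if (class == "HCC") params$ceus_enhancement_offset else 0
      tex[[class]] <- list(b = mb, c = mc)
    }
    gb <- 1 + stats::rnorm(1, 0, params$gain_sd[["bmode"]])
    gc_ <- 1 + stats::rnorm(1, 0, params$gain_sd[["ceus"]])
    frames[[fi]] <- list(
      bmode = clip8(gb * ifelse(mask, tex$HCC$b, tex$PAR$b)),
      ceus  = clip8(gc_ * ifelse(mask, tex$HCC$c, tex$PAR$c)))
    polys[[fi]] <- poly
  }
  structure(list(frames = frames, polygons = polys,
                 patient_id = sprintf("synthetic-%03d", seed)),
            class = "annotated_study")
}

#' @export
print.annotated_study <- function(x, ...) {
  d <- dim(x$frames[[1]]$bmode)
  cat(sprintf("<annotated_study> %s: %d frame pair(s), %dx%d px\n",
              x$patient_id, length(x$frames), d[1], d[2]))
  invisible(x)
}

#' Write a study to disk as PNG frames plus a VIA-style annotation file
#'
#' @param study an `annotated_study`.
#' @param dir output directory (created if missing).
#' @return invisibly, the path of the annotation JSON.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "annotated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- list()
  for (fi in seq_along(study$frames)) {
    for (ch in c("bmode", "ceus")) {
      fn <- sprintf("frame_%03d_%s.png", fi, ch)
      png::writePNG(study$frames[[fi]][[ch]] / 255, file.path(dir, fn))
    }
    ann[[fi]] <- list(frame_id = sprintf("frame_%03d_bmode.png", fi),
                      vertices = study$polygons[[fi]])
  }
  path <- file.path(dir, "annotations.json")
  write_via_annotations(ann, path)
  invisible(path)
}
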