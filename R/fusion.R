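#' Class probability pairs
#'
#' The unit of decision-level fusion: per-patch probabilities for the two
#' classes, (HCC, PAR), each row summing to 1.
#'
#' @param p_hcc,p_par numeric vectors in \[0, 1\] with `p_hcc + p_par = 1`
#'   (within 1e-9).
#' @return a numeric matrix with columns `HCC`, `PAR` and class
#'   `class_probabilities`.
#' @export
class_probabilities <- function(p_hcc, p_par = 1 - p_hcc) {
  stopifnot(length(p_hcc) == length(p_par))
  if (any(p_hcc < -1e-9 | p_hcc > 1 + 1e-9) || any(abs(p_hcc + p_par - 1) > 1e-9))
    stopf("probabilities must lie in [0,1] and sum to 1 per patch")
  structure(cbind(HCC = as.numeric(p_hcc), PAR = as.numeric(p_par)),
            class = c("class_probabilities", "matrix", "array"))
}

#' Pixelwise (feature-level) image fusion
#'
#' Fuses the two modality images of a pair into a single 8-bit image:
#' `arithmetic_mean` is `(b + c) / 2`; `weighted_mean` emphasizes the CEUS
#' channel, `(w_ceus * c + w_bmode * b) / (w_ceus + w_bmode)` with default
#' weights (2, 1), i.e. `(2c + b) / 3`; `multiplication` is `b * c` rescaled
#' by the fixed factor 255 (`round(b * c / 255)`), a deterministic, monotone
#' scaling to \[0, 255\] that is well defined for constant images. Results are
#' rounded to 8-bit.
#'
#' @param bmode,ceus matrices (or `size x size x n` arrays) of equal shape,
#'   8-bit gray levels.
#' @param method one of `"arithmetic_mean"`, `"weighted_mean"`,
#'   `"multiplication"`.
#' @param weights `c(w_ceus, w_bmode)` for the weighted mean; default `c(2, 1)`.
#' @return fused image(s) of the input shape.
#' @examples
#' fuse_images(matrix(30, 2, 2), matrix(90, 2, 2), "weighted_mean")  # all 70
#' @export
fuse_images <- function(bmode, ceus,
                        method = c("arithmetic_mean", "weighted_mean",
                                   "multiplication"),
                        weights = c(2, 1)) {
  method <- match.arg(method)
  if (!identical(dim(bmode), dim(ceus))) stopf("image shapes differ")
  if (any(weights <= 0)) stopf("weights must be positive")
  out <- switch(method,
    arithmetic_mean = (bmode + ceus) / 2,
    weighted_mean = (weights[1] * ceus + weights[2] * bmode) / sum(weights),
    multiplication = bmode * ceus / 255)
  clip8(out)
}

#' Feature-vector (classifier-level) fusion
#'
#' Combines the branch feature vectors of the two modalities.
#' `concatenation` appends them (lossless; lengths add). Elementwise methods
#' (`arithmetic_mean`, `weighted_mean` with CEUS weight 2, `multiplication`)
#' require equal lengths; when they differ, a fitted PCA `reducer` (see
#' [fit_pca_reduce()]) must be supplied and is applied to the longer vector
#' first. `kpca` concatenates and then projects through a fitted KPCA model
#' (see [fit_kpca()]) supplied as `reducer`.
#'
#' @param v_ceus,v_bmode numeric vectors (or matrices with one row per patch).
#' @param method fusion method.
#' @param weights `c(w_ceus, w_bmode)`, default `c(2, 1)`.
#' @param reducer a fitted [fit_pca_reduce()] reducer (elementwise methods on
#'   unequal lengths) or [fit_kpca()] model (`method = "kpca"`).
#' @return fused vector (or matrix, one row per patch).
#' @export
fuse_vectors <- function(v_ceus, v_bmode,
                         method = c("concatenation", "arithmetic_mean",
                                    "weighted_mean", "multiplication", "kpca"),
                         weights = c(2, 1), reducer = NULL) {
  method <- match.arg(method)
  vec_in <- is.null(dim(v_ceus)) && is.null(dim(v_bmode))
  if (is.null(dim(v_ceus))) v_ceus <- matrix(v_ceus, nrow = 1)
  if (is.null(dim(v_bmode))) v_bmode <- matrix(v_bmode, nrow = 1)
  if (nrow(v_ceus) != nrow(v_bmode)) stopf("patch counts differ between branches")
  if (method == "concatenation") {
    out <- cbind(v_ceus, v_bmode)
  } else if (method == "kpca") {
    if (is.null(reducer) || !inherits(reducer, "kpca_model"))
      stopf("method 'kpca' needs a fitted kpca_model as reducer")
    out <- transform_kpca(reducer, cbind(v_ceus, v_bmode))
  } else {
    if (ncol(v_ceus) != ncol(v_bmode)) {
      if (is.null(reducer) || !inherits(reducer, "pca_reducer"))
        stopf("elementwise fusion of unequal lengths needs a fitted pca_reducer for the longer side")
      if (ncol(v_ceus) > ncol(v_bmode)) v_ceus <- predict(reducer, v_ceus)
      else v_bmode <- predict(reducer, v_bmode)
      if (ncol(v_ceus) != ncol(v_bmode))
        stopf("reducer did not match the two branch dimensions")
    }
    if (any(weights <= 0)) stopf("weights must be positive")
    out <- switch(method,
      arithmetic_mean = (v_ceus + v_bmode) / 2,
      weighted_mean = (weights[1] * v_ceus + weights[2] * v_bmode) / sum(weights),
      multiplication = v_ceus * v_bmode)
  }
  if (vec_in) drop(out) else out
}

#' Decision-level fusion of class probabilities
#'
#' Per-class arithmetic mean, or CEUS-weighted mean `(2 p_ceus + p_bmode)/3`,
#' of the probability outputs of two fully separate classifiers. Output rows
#' are renormalized to machine precision.
#'
#' @param p_ceus,p_bmode [class_probabilities()] matrices (or length-2
#'   vectors (HCC, PAR)).
#' @param method `"arithmetic_mean"` or `"weighted_mean"`.
#' @param weights `c(w_ceus, w_bmode)`, default `c(2, 1)`.
#' @return a [class_probabilities()] matrix.
#' @examples
#' fuse_decisions(c(1, 0), c(0, 1))                    # (0.5, 0.5)
#' fuse_decisions(c(1, 0), c(0, 1), "weighted_mean")   # (2/3, 1/3)
#' @export
fuse_decisions <- function(p_ceus, p_bmode,
                           method = c("arithmetic_mean", "weighted_mean"),
                           weights = c(2, 1)) {
  method <- match.arg(method)
  as_cp <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    if (ncol(p) != 2) stopf("class probabilities need 2 columns (HCC, PAR)")
    if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-9))
      stopf("inputs must be normalized probability pairs")
    p
  }
  p1 <- as_cp(p_ceus); p2 <- as_cp(p_bmode)
  if (nrow(p1) != nrow(p2)) stopf("patch counts differ")
  if (any(weights <= 0)) stopf("weights must be positive")
  out <- switch(method,
    arithmetic_mean = (p1 + p2) / 2,
    weighted_mean = (weights[1] * p1 + weights[2] * p2) / sum(weights))
  out <- out / rowSums(out)
  class_probabilities(out[, 1], out[, 2])
}

#' Train a supervised head on fused features
#'
#' The classifier-level fusion head maps fused feature vectors to class
#' probabilities. `softmax` is multinomial logistic regression; `feedforward`
#' is a single-hidden-layer network; `svm` is a support vector machine whose
#' scores are calibrated to probabilities through a logistic link
#' (Platt scaling, as implemented in the underlying SVM fit).
#'
#' @param x numeric matrix of fused training features (rows = patches).
#' @param y labels (`HCC`/`PAR`).
#' @param head one of `"softmax"`, `"feedforward"`, `"svm"`.
#' @param hidden hidden-layer size for the feedforward head (default 8).
#' @param seed integer seed; fits are deterministic given it.
#' @return an object of class `fusion_head` with a [predict()] method
#'   returning [class_probabilities()].
#' @export
train_fusion_head <- function(x, y, head = c("softmax", "feedforward", "svm"),
                              hidden = 8L, seed = 1L) {
  head <- match.arg(head)
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("HCC", "PAR"))
  if (nlevels(droplevels(y)) < 2) stopf("training set must contain both classes")
  # standardize columns; constant columns pass through unscaled
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- switch(head,
    softmax = nnet::nnet(xs, stats::model.matrix(~ y - 1), size = 0,
                         skip = TRUE, softmax = TRUE, decay = 1e-4,
                         maxit = 200, trace = FALSE),
    feedforward = nnet::nnet(xs, stats::model.matrix(~ y - 1), size = hidden,
                             softmax = TRUE, decay = 5e-4, maxit = 300,
                             trace = FALSE),
    svm = e1071::svm(xs, y, kernel = "radial", probability = TRUE))
  structure(list(head = head, fit = fit, center = ctr, scale = scl,
                 levels = c("HCC", "PAR")), class = "fusion_head")
}

#' @export
predict.fusion_head <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  p <- if (object$head == "svm") {
    pr <- attr(stats::predict(object$fit, xs, probability = TRUE), "probabilities")
    pr[, c("HCC", "PAR"), drop = FALSE]
  } else {
    stats::predict(object$fit, xs)
  }
  p <- pmin(pmax(p, 0), 1)
  p <- p / rowSums(p)
  class_probabilities(p[, 1], p[, 2])
}

#' @export
print.fusion_head <- function(x, ...) {
  cat(sprintf("<fusion_head> %s head on %d features\n",
              x$head, length(x$center)))
  invisible(x)
}
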