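kernel_fun <- function(kernel, params) {
  switch(kernel,
    linear = function(X, Y) X %*% t(Y),
    polynomial_deg3 = function(X, Y) (X %*% t(Y) + params$offset)^params$degree,
    gaussian = function(X, Y) {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-params$gamma * pmax(d2, 0))
    },
    stopf("unknown kernel '%s'", kernel))
}

#' Fit kernel principal component analysis
#'
#' Eigen-decomposes the double-centered kernel matrix of the training vectors
#' and retains the `d` leading components. Eigenvectors are normalized so
#' that the embedding of a point x is
#' \eqn{y_k(x) = \sum_j \alpha_{kj} \tilde K(x, x_j)} with the projections of
#' the training set having variance \eqn{\lambda_k / n} per component. With
#' the linear kernel this reproduces classical PCA scores up to per-component
#' sign. Centering is performed in feature space (double centering of K and
#' consistent centering of out-of-sample kernel rows); negative numerical
#' eigenvalue residue is clipped at 0 and such components are dropped.
#'
#' @param X numeric matrix, one training vector per row (`n >= 2` rows).
#' @param kernel `"linear"`, `"polynomial_deg3"` (form `(x.y + 1)^3`) or
#'   `"gaussian"` (bandwidth `gamma`, default `1 / (2 * median pairwise
#'   distance^2)`).
#' @param d number of retained components, `d <= n`.
#' @param gamma optional Gaussian bandwidth override.
#' @return an object of class `kpca_model` with fields `alphas` (n x d),
#'   `lambdas`, `X` (training references), `kernel`, centering terms, and
#'   `embedding` (training scores).
#' @export
fit_kpca <- function(X, kernel = c("linear", "polynomial_deg3", "gaussian"),
                     d = 2L, gamma = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stopf("KPCA needs at least 2 training vectors")
  if (!is_count(d) || d > n) stopf("d must be a positive integer <= n (= %d)", n)
  params <- list(degree = 3, offset = 1)
  if (kernel == "gaussian") {
    if (is.null(gamma)) {
      dd <- stats::dist(X)
      med <- stats::median(dd)
      if (!is.finite(med) || med <= 0) med <- 1
      gamma <- 1 / (2 * med^2)
    }
    params$gamma <- gamma
  }
  kf <- kernel_fun(kernel, params)
  K <- kf(X, X)
  ones <- matrix(1 / n, n, n)
  Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
  Kc <- (Kc + t(Kc)) / 2
  eig <- eigen(Kc, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  keep <- which(lam > max(lam[1], 1) * 1e-12)[seq_len(min(d, sum(lam > 0)))]
  keep <- keep[!is.na(keep)]
  if (!length(keep)) stopf("kernel matrix has no positive eigenvalues")
  alphas <- sweep(eig$vectors[, keep, drop = FALSE], 2,
                  sqrt(lam[keep]), "/")
  emb <- Kc %*% alphas
  structure(list(kernel = kernel, kernel_params = params, alphas = alphas,
                 lambdas = lam[keep], X = X, d = length(keep),
                 K_colmeans = colMeans(K), K_mean = mean(K),
                 embedding = emb),
            class = "kpca_model")
}

#' Project vectors through a fitted KPCA model
#'
#' Computes the kernel row of each new vector against the training
#' references, applies the training centering terms, and projects onto the
#' retained eigenvectors. Transforming a training point reproduces its stored
#' embedding; with the linear kernel, transforming the training mean gives
#' the zero vector.
#'
#' @param model a [fit_kpca()] model.
#' @param x numeric vector (training dimensionality) or matrix of rows.
#' @return a `d`-column matrix of embeddings (a vector if `x` was a vector).
#' @export
transform_kpca <- function(model, x) {
  stopifnot(inherits(model, "kpca_model"))
  vec_in <- is.null(dim(x))
  x <- if (vec_in) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$X))
    stopf("input has %d columns; model was fitted on %d", ncol(x), ncol(model$X))
  kf <- kernel_fun(model$kernel, model$kernel_params)
  Kx <- kf(x, model$X)                      # m x n
  Kxc <- sweep(Kx, 2, model$K_colmeans) -
    matrix(rowMeans(Kx), nrow(Kx), ncol(Kx)) + model$K_mean
  out <- Kxc %*% model$alphas
  if (vec_in) drop(out) else out
}

#' @export
predict.kpca_model <- function(object, newdata, ...) transform_kpca(object, newdata)

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model> %s kernel, %d components fitted on %d x %d data\n",
              x$kernel, x$d, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Fit a linear PCA dimensionality reducer
#'
#' Projects onto the top `target_dim` principal components of the training
#' set. Used to match branch feature-vector lengths before elementwise
#' classifier-level fusion (fitted on training features only, then applied to
#' validation/test features).
#'
#' @param X numeric training matrix (rows = vectors).
#' @param target_dim retained dimension, `<= ncol(X)`.
#' @return an object of class `pca_reducer` with a [predict()] method.
#' @export
fit_pca_reduce <- function(X, target_dim) {
  X <- as.matrix(X)
  if (!is_count(target_dim) || target_dim > ncol(X))
    stopf("target_dim must be a positive integer <= %d", ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(target_dim, ncol(pc$rotation))
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev, target_dim = k),
            class = "pca_reducer")
}

#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  vec_in <- is.null(dim(newdata))
  x <- if (vec_in) matrix(newdata, nrow = 1) else as.matrix(newdata)
  out <- sweep(x, 2, object$center) %*% object$rotation
  if (vec_in) drop(out) else out
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat(sprintf("<pca_reducer> %d -> %d dimensions\n",
              nrow(x$rotation), x$target_dim))
  invisible(x)
}
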