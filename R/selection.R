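# entropy (base 2) of a discrete vector
entropy_disc <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# information gain of the class given a discrete feature
info_gain <- function(f, cls) {
  hc <- entropy_disc(cls)
  cond <- 0
  for (lv in unique(f)) {
    idx <- f == lv
    cond <- cond + mean(idx) * entropy_disc(cls[idx])
  }
  hc - cond
}

# symmetric uncertainty: 2 IG / (H(f) + H(c)); 0 when both entropies are 0
symm_uncertainty <- function(f, cls) {
  hf <- entropy_disc(f); hc <- entropy_disc(cls)
  if (hf + hc == 0) return(0)
  2 * info_gain(f, cls) / (hf + hc)
}

#' Equal-frequency discretization
#'
#' Bins each continuous feature into (up to) `bins` equal-frequency
#' intervals using sample quantiles; duplicate quantiles collapse. Already
#' discrete (few-valued) columns pass through unchanged. All entropy-based
#' selection in the package operates on this discretization.
#'
#' @param x numeric matrix or data frame of features.
#' @param bins number of bins (default 10).
#' @return integer matrix of bin codes.
#' @export
discretize_ef <- function(x, bins = 10L) {
  x <- as.matrix(x)
  apply(x, 2, function(col) {
    u <- unique(col)
    if (length(u) <= bins) return(match(col, sort(u)))
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(rep(1L, length(col)))
    as.integer(cut(col, br, include.lowest = TRUE))
  })
}

#' CFS merit of a feature subset
#'
#' Hall's correlation-based feature selection merit
#' `k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' feature-class correlation of the subset, `rff` the mean feature-feature
#' correlation, and `k` the subset size; correlations are symmetric
#' uncertainties on the discretized data. A subset of features strongly
#' correlated with the class but weakly correlated with each other scores
#' high.
#'
#' @param subset integer vector of feature column indices (non-empty).
#' @param x discretized feature matrix (see [discretize_ef()]).
#' @param y class labels.
#' @return scalar merit.
#' @export
cfs_merit <- function(subset, x, y) {
  if (!length(subset)) stopf("CFS merit is undefined for an empty subset")
  k <- length(subset)
  rcf <- mean(vapply(subset, function(j) symm_uncertainty(x[, j], y), 0))
  rff <- 0
  if (k > 1) {
    prs <- utils::combn(subset, 2)
    rff <- mean(vapply(seq_len(ncol(prs)), function(i)
      symm_uncertainty(x[, prs[1, i]], x[, prs[2, i]]), 0))
  }
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom == 0) return(0)
  k * rcf / denom
}

#' Correlation-based feature selection with best-first search
#'
#' Greedy best-first search over the subset lattice, starting from the empty
#' set, expanding the open subset of highest merit by single-feature
#' additions (with backtracking through the open list), and stopping after
#' 5 consecutive expansions without improvement of the best merit. Ties are
#' broken toward the lowest feature index, so the selection is deterministic
#' and invariant to feature order.
#'
#' @param x feature matrix or data frame (continuous features are
#'   discretized with [discretize_ef()]).
#' @param y class labels (2 classes required).
#' @param stale_limit expansions without improvement before stopping.
#' @return an object of class `selection_result` with `method = "cfs"`,
#'   `selected` (ordered feature indices) and `scores` (the best merit).
#' @export
best_first_cfs <- function(x, y, stale_limit = 5L) {
  xd <- discretize_ef(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stopf("need 2 classes for feature selection")
  p <- ncol(xd)
  key <- function(s) if (length(s)) paste(sort(s), collapse = ",") else "<empty>"
  visited <- new.env(hash = TRUE)
  # open list: subsets with merits; start at the empty set (merit 0)
  open_sets <- list(integer(0)); open_merits <- 0
  assign(key(integer(0)), TRUE, envir = visited)
  best_set <- integer(0); best_merit <- 0; stale <- 0L
  while (length(open_sets) && stale < stale_limit) {
    i <- which.max(open_merits)
    cur <- open_sets[[i]]
    open_sets[[i]] <- NULL; open_merits <- open_merits[-i]
    improved <- FALSE
    for (j in seq_len(p)) {
      if (j %in% cur) next
      cand <- c(cur, j)
      kk <- key(cand)
      if (!is.null(visited[[kk]])) next
      assign(kk, TRUE, envir = visited)
      m <- cfs_merit(cand, xd, y)
      open_sets[[length(open_sets) + 1L]] <- cand
      open_merits <- c(open_merits, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- cand
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(method = "cfs", selected = sort(best_set),
                 scores = best_merit),
            class = "selection_result")
}

#' Gain-ratio feature ranking
#'
#' Per-feature gain ratio = information gain / split information on the
#' discretized data (defined as 0 when the split information is 0, e.g. for
#' a constant feature). Features are ranked in descending order and those
#' with gain ratio strictly above `threshold` are kept (default cutoff
#' 0.15). A feature identical to the class scores 1.
#'
#' @param x feature matrix or data frame.
#' @param y class labels.
#' @param threshold retention cutoff (default 0.15).
#' @return an object of class `selection_result` with `selected` (kept
#'   feature indices, ordered by original index) and `scores` (gain ratio
#'   per feature, named by column).
#' @export
gain_ratio_rank <- function(x, y, threshold = 0.15) {
  xd <- discretize_ef(x)
  y <- as.factor(y)
  gr <- apply(xd, 2, function(f) {
    si <- entropy_disc(f)
    if (si == 0) return(0)
    info_gain(f, y) / si
  })
  names(gr) <- colnames(x)
  structure(list(method = "gain_ratio",
                 selected = which(gr > threshold),
                 scores = gr, threshold = threshold),
            class = "selection_result")
}

#' Union of relevant feature subsets
#'
#' Set union of the selections of several methods, ordered by original
#' feature index -- the combined relevant set fed to the conventional
#' classifiers.
#'
#' @param ... `selection_result` objects over the same feature space.
#' @return an object of class `selection_result` with `method = "union"`.
#' @export
union_relevant <- function(...) {
  rs <- list(...)
  stopifnot(length(rs) >= 1)
  sel <- sort(unique(unlist(lapply(rs, function(r) {
    stopifnot(inherits(r, "selection_result"))
    as.integer(r$selected)
  }))))
  structure(list(method = "union", selected = sel, scores = NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s) selected\n",
              x$method, length(x$selected)))
  if (length(x$selected)) cat(" indices:", x$selected, "\n")
  invisible(x)
}
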