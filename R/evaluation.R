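#' Stratified train/validation/test split
#'
#' Splits patch indices into train/validation/test parts, stratified by
#' class to within one patch. With `group_ids`, all members of a group (for
#' example a source patch and its rotated copies) are kept on the same side,
#' preventing augmentation leakage across splits.
#'
#' @param labels class labels per patch.
#' @param fractions length-3 vector summing to 1; `c(0.60, 0.15, 0.25)` for
#'   CNN experiments, `c(0.75, 0, 0.25)` for the conventional baseline.
#' @param seed integer seed.
#' @param group_ids optional vector of group identifiers per patch.
#' @return object of class `data_split`: list with integer index vectors
#'   `train`, `validation`, `test`.
#' @export
split_data <- function(labels, fractions = c(0.60, 0.15, 0.25), seed = 1L,
                       group_ids = NULL) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  labels <- as.factor(labels)
  n <- length(labels)
  if (is.null(group_ids)) group_ids <- seq_len(n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  # stratify at the group level; a group's class = its first member's class
  for (cls in levels(labels)) {
    gids <- unique(group_ids[labels == cls])
    gids <- sample(gids)
    ng <- length(gids)
    n_tr <- round(fractions[1] * ng)
    n_va <- round(fractions[2] * ng)
    n_tr <- min(n_tr, ng); n_va <- min(n_va, ng - n_tr)
    asg <- rep(3L, ng)
    if (n_tr > 0) asg[seq_len(n_tr)] <- 1L
    if (n_va > 0) asg[n_tr + seq_len(n_va)] <- 2L
    for (k in 1:3) {
      gs <- gids[asg == k]
      parts[[k]] <- c(parts[[k]], which(labels == cls & group_ids %in% gs))
    }
  }
  parts <- lapply(parts, sort)
  if (sum(lengths(parts)) != n) stopf("split is not a partition")  # defensive
  for (k in 1:3) {
    if (fractions[k] > 0 && length(parts[[k]]) &&
        length(unique(labels[parts[[k]]])) < nlevels(droplevels(labels)))
      warning(sprintf("part '%s' does not contain every class",
                      names(parts)[k]))
  }
  structure(c(parts, list(fractions = fractions)), class = "data_split")
}

#' Confusion matrix of a 2-class prediction
#'
#' Positive class = HCC throughout.
#'
#' @param predicted,truth label vectors (`HCC`/`PAR`).
#' @return object of class `confusion_matrix` with fields `tp`, `fn`, `tn`,
#'   `fp`.
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- factor(as.character(predicted), levels = c("HCC", "PAR"))
  truth <- factor(as.character(truth), levels = c("HCC", "PAR"))
  structure(list(tp = sum(predicted == "HCC" & truth == "HCC"),
                 fn = sum(predicted == "PAR" & truth == "HCC"),
                 tn = sum(predicted == "PAR" & truth == "PAR"),
                 fp = sum(predicted == "HCC" & truth == "PAR")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("HCC", "PAR"),
                              predicted = c("HCC", "PAR")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (tp + tn) / total`, `sensitivity = tp / (tp + fn)` (recall of
#' the HCC class), `specificity = tn / (tn + fp)`. Ratios with zero
#' denominators are reported as 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector (proportions in \[0, 1\]).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$tn + cm$fp
  if (total == 0) stopf("empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (empty denominator); reporting 0", what))
      return(0)
    }
    num / den
  }
  c(accuracy = (cm$tp + cm$tn) / total,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = ratio(cm$tn, cm$tn + cm$fp, "specificity"))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (probability of the
#' HCC class) and plots sensitivity against 1 - specificity; the AUC is the
#' trapezoidal area, equal to the normalized Mann--Whitney U statistic.
#'
#' @param scores numeric vector, probability (or score) of HCC per patch.
#' @param labels true labels (`HCC`/`PAR`, both present).
#' @return list with `curve` (data frame `threshold`, `fpr`, `tpr`,
#'   monotone from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("HCC", "PAR"))
  npos <- sum(labels == "HCC"); nneg <- sum(labels == "PAR")
  if (npos == 0 || nneg == 0) stopf("AUC undefined: both classes required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == "HCC") / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == "PAR") / nneg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Plot overlaid ROC curves
#'
#' @param rocs named list of [roc_auc()] results.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_roc <- function(rocs, main = "ROC") {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "gray",
                 xlab = "1 - specificity", ylab = "sensitivity", main = main)
  cols <- grDevices::hcl.colors(max(3, length(rocs)), "Dark 3")
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$curve$fpr, rocs[[i]]$curve$tpr, col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", names(rocs),
                                    vapply(rocs, `[[`, 0, "auc")),
                   col = cols[seq_along(rocs)], lwd = 2, bty = "n")
  invisible(NULL)
}

decide <- function(p_hcc) ifelse(p_hcc >= 0.5, "HCC", "PAR")  # ties -> HCC

eval_probs <- function(p, truth) {
  cm <- confusion_matrix(decide(p[, "HCC"]), truth)
  c(confusion_metrics(cm), auc = roc_auc(p[, "HCC"], truth)$auc)
}

#' Run a grid of single-modality and fusion experiments
#'
#' Trains CNN branches on a patch collection under a shared stratified
#' 60/15/25 split and evaluates each requested configuration on the test
#' (and validation) set. Trained branches are cached and reused across
#' configurations (decision-level fusion reuses the two single-modality
#' branches). Each config is a list with entries:
#' \describe{
#'   \item{level}{`"single"`, `"feature"`, `"classifier"`, or `"decision"`.}
#'   \item{modality}{for `single`: `"bmode"` or `"ceus"`.}
#'   \item{method}{fusion method: image fusion methods for `feature`,
#'     [fuse_vectors()] methods for `classifier`, mean type for `decision`.}
#'   \item{backbone}{backbone name (default `"tiny"`).}
#'   \item{head}{fusion head for `classifier` level (default `"softmax"`).}
#'   \item{kpca_dim}{retained KPCA dimension (default 128, capped at the
#'     training size).}
#' }
#'
#' @param patches a [paired_patches()] collection.
#' @param configs list of configuration lists.
#' @param train_cfg a [train_config()].
#' @param fractions split fractions (default `c(0.6, 0.15, 0.25)`).
#' @param seed split seed.
#' @return a data frame with one row per configuration: test and validation
#'   accuracy/sensitivity/specificity/AUC.
#' @export
run_experiment_grid <- function(patches, configs,
                                train_cfg = train_config(),
                                fractions = c(0.6, 0.15, 0.25), seed = 1L) {
  stopifnot(inherits(patches, "paired_patches"))
  sp <- split_data(patches$label, fractions, seed = seed)
  tr <- patches[sp$train]; te <- patches[sp$test]
  va <- if (length(sp$validation)) patches[sp$validation]
  branches <- new.env(parent = emptyenv())
  get_branch <- function(backbone, channel, fuse_method = NULL) {
    key <- paste(backbone, channel, fuse_method %||% "", sep = "|")
    if (!is.null(branches[[key]])) return(branches[[key]])
    trn <- tr
    if (channel == "fused") trn <- fuse_patches(trn, fuse_method)
    mod <- build_backbone(backbone, seed = train_cfg$seed)
    mod <- train_branch(mod, trn, channel, train_cfg)
    branches[[key]] <- mod
    mod
  }
  rows <- list()
  for (cfg in configs) {
    level <- cfg$level %||% "single"
    backbone <- cfg$backbone %||% "tiny"
    head <- cfg$head %||% "softmax"
    method <- cfg$method %||% switch(level, feature = "arithmetic_mean",
                                     classifier = "concatenation",
                                     decision = "arithmetic_mean", NA)
    prob_on <- function(set) {
      switch(level,
        single = predict_probabilities(get_branch(backbone, cfg$modality),
                                       set, cfg$modality),
        feature = predict_probabilities(
          get_branch(backbone, "fused", method),
          fuse_patches(set, method), "fused"),
        decision = fuse_decisions(
          predict_probabilities(get_branch(backbone, "ceus"), set, "ceus"),
          predict_probabilities(get_branch(backbone, "bmode"), set, "bmode"),
          method),
        classifier = {
          bc <- get_branch(backbone, "ceus"); bb <- get_branch(backbone, "bmode")
          f_tr_c <- extract_features(bc, tr, "ceus")
          f_tr_b <- extract_features(bb, tr, "bmode")
          reducer <- NULL
          if (method == "kpca") {
            d <- min(cfg$kpca_dim %||% 128L, nrow(f_tr_c))
            reducer <- fit_kpca(cbind(f_tr_c, f_tr_b), "linear", d = d)
          } else if (method != "concatenation" &&
                     ncol(f_tr_c) != ncol(f_tr_b)) {
            long <- if (ncol(f_tr_c) > ncol(f_tr_b)) f_tr_c else f_tr_b
            reducer <- fit_pca_reduce(long, min(ncol(f_tr_c), ncol(f_tr_b)))
          }
          fused_tr <- fuse_vectors(f_tr_c, f_tr_b, method, reducer = reducer)
          hd <- train_fusion_head(fused_tr, tr$label, head,
                                  seed = train_cfg$seed)
          fused_set <- fuse_vectors(extract_features(bc, set, "ceus"),
                                    extract_features(bb, set, "bmode"),
                                    method, reducer = reducer)
          predict(hd, fused_set)
        },
        stopf("unknown level '%s'", level))
    }
    m_te <- eval_probs(prob_on(te), te$label)
    m_va <- if (!is.null(va)) eval_probs(prob_on(va), va$label) else
      rep(NA_real_, 4)
    rows[[length(rows) + 1L]] <- data.frame(
      level = level, modality = cfg$modality %||% NA_character_,
      method = method, backbone = backbone,
      head = if (level == "classifier") head else NA_character_,
      accuracy = m_te[["accuracy"]], sensitivity = m_te[["sensitivity"]],
      specificity = m_te[["specificity"]], auc = m_te[["auc"]],
      val_accuracy = m_va[[1]], val_sensitivity = m_va[[2]],
      val_specificity = m_va[[3]], val_auc = m_va[[4]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
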