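test_that("stratified splits hit the requested fractions per class", {
  labels <- rep(c("HCC", "PAR"), each = 100)
  sp <- split_data(labels, c(0.60, 0.15, 0.25), seed = 1)
  for (cls in c("HCC", "PAR")) {
    expect_identical(sum(labels[sp$train] == cls), 60L)
    expect_identical(sum(labels[sp$validation] == cls), 15L)
    expect_identical(sum(labels[sp$test] == cls), 25L)
  }
  # partition: disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_along(labels))
  sp1 <- split_data(labels, c(1, 0, 0), seed = 2)
  expect_identical(sort(sp1$train), seq_along(labels))
  expect_length(sp1$test, 0)
  expect_error(split_data(labels, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("grouped splits keep augmented copies on one side", {
  labels <- rep(rep(c("HCC", "PAR"), each = 25), times = 4)
  groups <- rep(seq_len(50), times = 4)  # 4 rotated copies per source patch
  sp <- split_data(labels, c(0.6, 0.15, 0.25), seed = 3, group_ids = groups)
  for (part in list(sp$train, sp$validation, sp$test)) {
    gs <- unique(groups[part])
    expect_identical(sort(part), sort(which(groups %in% gs)))
  }
})

test_that("confusion metrics reproduce their closed forms", {
  perfect <- confusion_matrix(rep(c("HCC", "PAR"), each = 10),
                              rep(c("HCC", "PAR"), each = 10))
  expect_equal(confusion_metrics(perfect),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  always_hcc <- confusion_matrix(rep("HCC", 20),
                                 rep(c("HCC", "PAR"), each = 10))
  expect_warning(m <- confusion_metrics(always_hcc), NA)
  expect_equal(m, c(accuracy = 0.5, sensitivity = 1, specificity = 0))
  set.seed(35)
  pred <- sample(c("HCC", "PAR"), 50, TRUE)
  truth <- sample(c("HCC", "PAR"), 50, TRUE)
  cm <- confusion_matrix(pred, truth)
  expect_identical(cm$tp + cm$fn + cm$tn + cm$fp, 50L)
  m <- confusion_metrics(cm)
  expect_equal(m[["accuracy"]], mean(pred == truth))
  expect_equal(m[["sensitivity"]],
               sum(pred == "HCC" & truth == "HCC") / sum(truth == "HCC"))
})

test_that("ROC/AUC equals the rank statistic and is properly bounded", {
  lab <- rep(c("HCC", "PAR"), each = 5)
  r <- roc_auc(c(rep(0.9, 5), rep(0.1, 5)), lab)
  expect_equal(r$auc, 1)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  # AUC == normalized Mann-Whitney U with ties, on random small inputs
  set.seed(36)
  for (i in 1:10) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    sc <- round(runif(n1 + n2), 2)  # force ties
    lb <- c(rep("HCC", n1), rep("PAR", n2))
    pos <- sc[lb == "HCC"]; neg <- sc[lb == "PAR"]
    u <- 0
    for (a in pos) for (b in neg)
      u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(sc, lb)$auc, u / (n1 * n2), tolerance = 1e-12)
  }
  # independent labels give AUC ~ 0.5
  set.seed(37)
  sc <- runif(2000)
  lb <- sample(c("HCC", "PAR"), 2000, TRUE)
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.05)
  expect_error(roc_auc(runif(5), rep("HCC", 5)), "both classes")
})

test_that("our AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  sc <- runif(80)
  lb <- sample(c("HCC", "PAR"), 80, TRUE)
  ref <- suppressMessages(pROC::auc(pROC::roc(lb, sc, levels = c("PAR", "HCC"),
                                              direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("metrics are invariant to patch ordering", {
  set.seed(39)
  sc <- runif(40); lb <- sample(c("HCC", "PAR"), 40, TRUE)
  perm <- sample(40)
  expect_equal(roc_auc(sc, lb)$auc, roc_auc(sc[perm], lb[perm])$auc)
  m1 <- confusion_metrics(confusion_matrix(ifelse(sc > 0.5, "HCC", "PAR"), lb))
  m2 <- confusion_metrics(confusion_matrix(ifelse(sc[perm] > 0.5, "HCC", "PAR"),
                                           lb[perm]))
  expect_equal(m1, m2)
})

test_that("the experiment grid returns one evaluated row per config", {
  d <- generate_paired_patches(synthetic_params(seed = 40, n_per_class = 30))
  cfg <- tiny_train_config(seed = 1, epochs = 3)
  res <- run_experiment_grid(d, list(
    list(level = "single", modality = "bmode"),
    list(level = "single", modality = "ceus"),
    list(level = "feature", method = "weighted_mean"),
    list(level = "decision", method = "arithmetic_mean")), cfg, seed = 4)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(is.finite(res$val_accuracy)))
})
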