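#' Conventional-classifier configuration
#'
#' Settings of the texture-feature baseline heads: polynomial-kernel SVM
#' (degree 1, 3 or 5), multilayer perceptron (up to 3 hidden layers with
#' node count = the rounded mean of the class count and the feature count,
#' minimum 2; 500 training epochs), AdaBoost over decision trees
#' (100 iterations), and random forest (100 trees).
#'
#' @param method `"svm_poly"`, `"mlp"`, `"adaboost_trees"`, `"random_forest"`.
#' @param svm_degree polynomial degree (1, 3 or 5).
#' @param mlp_layers hidden layers (1--3; layers beyond the first reuse the
#'   same node count).
#' @param iterations boosting iterations / forest size.
#' @param epochs MLP training epochs.
#' @param seed integer seed.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("random_forest", "svm_poly", "mlp",
                                       "adaboost_trees"),
                            svm_degree = 3L, mlp_layers = 1L,
                            iterations = 100L, epochs = 500L, seed = 1L) {
  method <- match.arg(method)
  if (!svm_degree %in% c(1L, 3L, 5L)) stopf("svm_degree must be 1, 3 or 5")
  stopifnot(mlp_layers >= 1, mlp_layers <= 3, is_count(iterations),
            is_count(epochs))
  structure(list(method = method, svm_degree = as.integer(svm_degree),
                 mlp_layers = as.integer(mlp_layers),
                 iterations = as.integer(iterations),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "baseline_config")
}

# AdaBoost.M1 over rpart trees; probabilities are normalized weighted vote
# shares of the ensemble.
fit_adaboost <- function(x, y, iterations) {
  df <- data.frame(x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(iterations)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        method = "class",
                        control = rpart::rpart.control(cp = 0.001,
                                                       maxdepth = 5,
                                                       minsplit = 4))
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break
    if (err < 1e-10) {
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, 10)  # essentially-perfect learner dominates
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  if (!length(trees)) {  # weak learner no better than chance at once
    trees <- list(rpart::rpart(y ~ ., data = cbind(df, y = y),
                               method = "class"))
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas), class = "adaboost_m1")
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  vote <- numeric(nrow(df))
  for (m in seq_along(model$trees)) {
    pred <- stats::predict(model$trees[[m]], df, type = "class")
    vote <- vote + model$alphas[m] * ifelse(pred == "HCC", 1, -1)
  }
  total <- sum(model$alphas)
  p <- (vote / total + 1) / 2
  pmin(pmax(p, 0), 1)
}

#' Fit a conventional classifier on texture features and evaluate it
#'
#' Uniform interface over the baseline heads: every method returns
#' normalized HCC/PAR probabilities on the test set plus confusion-matrix
#' metrics and AUC. Deterministic given `config$seed`.
#'
#' @param x_train,x_test numeric feature matrices (selected features).
#' @param y_train,y_test labels (`HCC`/`PAR`).
#' @param config a [baseline_config()].
#' @return list with `probabilities` ([class_probabilities()] on the test
#'   set), `metrics` (accuracy, sensitivity, specificity, auc), and the
#'   fitted `model`.
#' @export
fit_predict_baseline <- function(x_train, y_train, x_test, y_test,
                                 config = baseline_config()) {
  stopifnot(inherits(config, "baseline_config"))
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(as.character(y_train), levels = c("HCC", "PAR"))
  y_test <- factor(as.character(y_test), levels = c("HCC", "PAR"))
  if (nlevels(droplevels(y_train)) < 2)
    stopf("training data must contain both classes")
  ctr <- colMeans(x_train); scl <- apply(x_train, 2, stats::sd)
  scl[scl == 0] <- 1
  xtr <- scale(x_train, ctr, scl); xte <- scale(x_test, ctr, scl)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  p_hcc <- switch(config$method,
    svm_poly = {
      fit <- e1071::svm(xtr, y_train, kernel = "polynomial",
                        degree = config$svm_degree, coef0 = 1,
                        probability = TRUE)
      attr(stats::predict(fit, xte, probability = TRUE),
           "probabilities")[, "HCC"]
    },
    mlp = {
      nodes <- max(2L, round(mean(c(2L, ncol(xtr)))))
      fit <- nnet::nnet(xtr, labels_to_onehot(y_train), size = nodes,
                        softmax = TRUE, decay = 1e-4,
                        maxit = config$epochs, trace = FALSE)
      stats::predict(fit, xte)[, "HCC"]
    },
    adaboost_trees = {
      fit <- fit_adaboost(xtr, y_train, config$iterations)
      predict_adaboost(fit, xte)
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, y_train,
                                        ntree = config$iterations)
      stats::predict(fit, xte, type = "prob")[, "HCC"]
    })
  probs <- class_probabilities(p_hcc)
  metrics <- eval_probs(probs, y_test)
  list(probabilities = probs, metrics = metrics,
       model = if (exists("fit", inherits = FALSE)) fit)
}
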