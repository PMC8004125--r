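# --- architecture builders --------------------------------------------------

fire_module <- function(prefix, input, s, e) {
  list(nd_conv(paste0(prefix, "_squeeze"), input, 1L, s, act = "relu"),
       nd_conv(paste0(prefix, "_e1"), paste0(prefix, "_squeeze"), 1L, e, act = "relu"),
       nd_conv(paste0(prefix, "_e3"), paste0(prefix, "_squeeze"), 3L, e,
               pad = 1L, act = "relu"),
       nd_concat(prefix, c(paste0(prefix, "_e1"), paste0(prefix, "_e3"))))
}

build_squeezenet <- function() {
  nodes <- c(
    list(nd_conv("conv1", ".input", 3L, 64L, stride = 2L, act = "relu"),
         nd_pool("pool1", "conv1", "max", 3L, 2L, ceil_mode = TRUE)),
    fire_module("fire2", "pool1", 16L, 64L),
    fire_module("fire3", "fire2", 16L, 64L),
    list(nd_pool("pool3", "fire3", "max", 3L, 2L, ceil_mode = TRUE)),
    fire_module("fire4", "pool3", 32L, 128L),
    fire_module("fire5", "fire4", 32L, 128L),
    list(nd_pool("pool5", "fire5", "max", 3L, 2L, ceil_mode = TRUE)),
    fire_module("fire6", "pool5", 48L, 192L),
    fire_module("fire7", "fire6", 48L, 192L),
    fire_module("fire8", "fire7", 64L, 256L),
    fire_module("fire9", "fire8", 64L, 256L),
    list(nd_conv("relu_conv10", "fire9", 1L, 2L, act = "relu"),
         nd_gap("pool10", "relu_conv10"),
         nd_softmax("softmax", "pool10")))
  nn_model("squeezenet", list(h = 227L, w = 227L, c = 3L), nodes,
           tap = "relu_conv10", classifier = "pool10")
}

inception_module <- function(prefix, input, c1, c3r, c3, c5r, c5, cp) {
  p <- function(x) paste0(prefix, "_", x)
  list(nd_conv(p("b1"), input, 1L, c1, act = "relu"),
       nd_conv(p("b3r"), input, 1L, c3r, act = "relu"),
       nd_conv(p("b3"), p("b3r"), 3L, c3, pad = 1L, act = "relu"),
       nd_conv(p("b5r"), input, 1L, c5r, act = "relu"),
       nd_conv(p("b5"), p("b5r"), 5L, c5, pad = 2L, act = "relu"),
       nd_pool(p("pool"), input, "max", 3L, 1L, pad = 1L),
       nd_conv(p("bp"), p("pool"), 1L, cp, act = "relu"),
       nd_concat(prefix, c(p("b1"), p("b3"), p("b5"), p("bp"))))
}

googlenet_stem <- function() {
  c(list(nd_conv("conv1", ".input", 7L, 64L, stride = 2L, pad = 3L, act = "relu"),
         nd_pool("pool1", "conv1", "max", 3L, 2L, ceil_mode = TRUE),
         nd_conv("conv2", "pool1", 1L, 64L, act = "relu"),
         nd_conv("conv3", "conv2", 3L, 192L, pad = 1L, act = "relu"),
         nd_pool("pool2", "conv3", "max", 3L, 2L, ceil_mode = TRUE)),
    inception_module("icp3a", "pool2", 64L, 96L, 128L, 16L, 32L, 32L),
    inception_module("icp3b", "icp3a", 128L, 128L, 192L, 32L, 96L, 64L),
    list(nd_pool("pool3", "icp3b", "max", 3L, 2L, ceil_mode = TRUE)),
    inception_module("icp4a", "pool3", 192L, 96L, 208L, 16L, 48L, 64L),
    inception_module("icp4b", "icp4a", 160L, 112L, 224L, 24L, 64L, 64L),
    inception_module("icp4c", "icp4b", 128L, 128L, 256L, 24L, 64L, 64L),
    inception_module("icp4d", "icp4c", 112L, 144L, 288L, 32L, 64L, 64L))
}

build_googlenet <- function() {
  nodes <- c(
    googlenet_stem(),
    inception_module("icp4e", "icp4d", 256L, 160L, 320L, 32L, 128L, 128L),
    list(nd_pool("pool4", "icp4e", "max", 3L, 2L, ceil_mode = TRUE)),
    inception_module("icp5a", "pool4", 256L, 160L, 320L, 32L, 128L, 128L),
    inception_module("icp5b", "icp5a", 384L, 192L, 384L, 48L, 128L, 128L),
    list(nd_gap("pool5-drop_7X7_s1", "icp5b"),
         nd_fc("fc_out", "pool5-drop_7X7_s1", 2L),
         nd_softmax("softmax", "fc_out")))
  nn_model("googlenet", list(h = 224L, w = 224L, c = 3L), nodes,
           tap = "pool5-drop_7X7_s1", classifier = "fc_out")
}

# GoogLeNet variant: residual shortcuts skip past the last three inception
# modules -- each of their outputs is average-pooled to a vector, passed
# through a 1x1 convolution (here: a linear map) to the 2-class output width,
# and summed with the main classifier output. The branch feature tap is the
# pooled output of the 528-wide inception module preceding the skipped ones.
build_googlenet_v1 <- function() {
  nodes <- c(
    googlenet_stem(),
    list(nd_gap("pool_4d", "icp4d")),
    inception_module("icp4e", "icp4d", 256L, 160L, 320L, 32L, 128L, 128L),
    list(nd_pool("pool4", "icp4e", "max", 3L, 2L, ceil_mode = TRUE)),
    inception_module("icp5a", "pool4", 256L, 160L, 320L, 32L, 128L, 128L),
    inception_module("icp5b", "icp5a", 384L, 192L, 384L, 48L, 128L, 128L),
    list(nd_gap("gap_4e", "icp4e"), nd_fc("skip_4e", "gap_4e", 2L),
         nd_gap("gap_5a", "icp5a"), nd_fc("skip_5a", "gap_5a", 2L),
         nd_gap("gap_5b", "icp5b"), nd_fc("main_5b", "gap_5b", 2L),
         nd_add("fc_out", c("main_5b", "skip_4e", "skip_5a")),
         nd_softmax("softmax", "fc_out")))
  nn_model("googlenet_v1", list(h = 224L, w = 224L, c = 3L), nodes,
           tap = "pool_4d", classifier = "fc_out")
}

res_block <- function(prefix, input, cout, stride = 1L, downsample = FALSE) {
  p <- function(x) paste0(prefix, "_", x)
  nodes <- list(
    nd_conv(p("c1"), input, 3L, cout, stride = stride, pad = 1L, act = "relu"),
    nd_conv(p("c2"), p("c1"), 3L, cout, pad = 1L))
  skip <- input
  if (downsample) {
    nodes <- c(nodes, list(nd_conv(p("down"), input, 1L, cout, stride = stride)))
    skip <- p("down")
  }
  c(nodes, list(nd_add(p("add"), c(p("c2"), skip)),
                nd_relu(prefix, p("add"))))
}

build_resnet18 <- function() {
  nodes <- c(
    list(nd_conv("conv1", ".input", 7L, 64L, stride = 2L, pad = 3L, act = "relu"),
         nd_pool("pool1", "conv1", "max", 3L, 2L, pad = 1L)),
    res_block("res2a", "pool1", 64L),
    res_block("res2b", "res2a", 64L),
    res_block("res3a", "res2b", 128L, stride = 2L, downsample = TRUE),
    res_block("res3b", "res3a", 128L),
    res_block("res4a", "res3b", 256L, stride = 2L, downsample = TRUE),
    res_block("res4b", "res4a", 256L),
    res_block("res5a", "res4b", 512L, stride = 2L, downsample = TRUE),
    res_block("res5b", "res5a", 512L),
    list(nd_gap("pool5", "res5b"),
         nd_fc("fc_out", "pool5", 2L),
         nd_softmax("softmax", "fc_out")))
  nn_model("resnet18", list(h = 224L, w = 224L, c = 3L), nodes,
           tap = "pool5", classifier = "fc_out")
}

build_vgg16 <- function() {
  cfg <- list(c(64, 64), c(128, 128), c(256, 256, 256),
              c(512, 512, 512), c(512, 512, 512))
  nodes <- list()
  prev <- ".input"
  for (b in seq_along(cfg)) {
    for (j in seq_along(cfg[[b]])) {
      nm <- sprintf("conv%d_%d", b, j)
      nodes <- c(nodes, list(nd_conv(nm, prev, 3L, cfg[[b]][j], pad = 1L,
                                     act = "relu")))
      prev <- nm
    }
    nm <- sprintf("pool%d", b)
    nodes <- c(nodes, list(nd_pool(nm, prev, "max", 2L, 2L)))
    prev <- nm
  }
  nodes <- c(nodes, list(
    nd_fc("fc6", prev, 4096L, act = "relu"),
    nd_fc("drop7", "fc6", 4096L, act = "relu"),  # dropout = identity at inference
    nd_fc("fc_out", "drop7", 2L),
    nd_softmax("softmax", "fc_out")))
  nn_model("vgg16", list(h = 224L, w = 224L, c = 3L), nodes,
           tap = "drop7", classifier = "fc_out")
}

build_densenet201 <- function() {
  growth <- 32L
  blocks <- c(6L, 12L, 48L, 32L)
  nodes <- list(
    nd_conv("conv1", ".input", 7L, 64L, stride = 2L, pad = 3L, act = "relu"),
    nd_pool("pool1", "conv1", "max", 3L, 2L, pad = 1L))
  prev <- "pool1"; ch <- 64L
  for (b in seq_along(blocks)) {
    for (l in seq_len(blocks[b])) {
      p <- sprintf("d%d_%d", b, l)
      nodes <- c(nodes, list(
        nd_conv(paste0(p, "_bottleneck"), prev, 1L, 4L * growth, act = "relu"),
        nd_conv(paste0(p, "_conv"), paste0(p, "_bottleneck"), 3L, growth,
                pad = 1L, act = "relu"),
        nd_concat(p, c(prev, paste0(p, "_conv")))))
      prev <- p; ch <- ch + growth
    }
    if (b < length(blocks)) {
      tr <- sprintf("trans%d", b)
      ch <- ch %/% 2L
      nodes <- c(nodes, list(
        nd_conv(paste0(tr, "_conv"), prev, 1L, ch, act = "relu"),
        nd_pool(tr, paste0(tr, "_conv"), "avg", 2L, 2L)))
      prev <- tr
    }
  }
  nodes <- c(nodes, list(nd_gap("avg_pool", prev),
                         nd_fc("fc_out", "avg_pool", 2L),
                         nd_softmax("softmax", "fc_out")))
  nn_model("densenet201", list(h = 224L, w = 224L, c = 3L), nodes,
           tap = "avg_pool", classifier = "fc_out")
}

build_tiny <- function() {
  nodes <- list(
    nd_conv("conv1", ".input", 5L, 8L, act = "relu"),
    nd_pool("pool1", "conv1", "max", 2L, 2L),
    nd_conv("conv2", "pool1", 3L, 16L, act = "relu"),
    nd_pool("pool2", "conv2", "max", 2L, 2L),
    nd_conv("conv3", "pool2", 3L, 64L, act = "relu"),
    nd_gap("gap", "conv3"),
    nd_fc("fc_out", "gap", 2L),
    nd_softmax("softmax", "fc_out"))
  nn_model("tiny", list(h = 51L, w = 51L, c = 1L), nodes,
           tap = "gap", classifier = "fc_out")
}

#' Backbone registry
#'
#' Names, native input sizes, tap layers and expected flattened tap-vector
#' lengths of the available CNN branch architectures. The tap layer is the
#' layer whose flattened output serves as a branch's feature vector for
#' classifier-level fusion; for SqueezeNet both the 392-length
#' `relu_conv10` map and the 2-length `pool10` output are available (their
#' concatenation has length 394).
#'
#' @return a data frame with columns `name`, `native_input`, `tap_layer`,
#'   `tap_dim`, `n_outputs`.
#' @export
backbone_registry <- function() {
  data.frame(
    name = c("squeezenet", "googlenet", "googlenet_v1", "resnet18",
             "vgg16", "densenet201", "tiny"),
    native_input = c(227L, 224L, 224L, 224L, 224L, 224L, 51L),
    tap_layer = c("relu_conv10", "pool5-drop_7X7_s1", "pool_4d", "pool5",
                  "drop7", "avg_pool", "gap"),
    tap_dim = c(392L, 1024L, 528L, 512L, 4096L, 1920L, 64L),
    n_outputs = 2L,
    stringsAsFactors = FALSE)
}

#' Construct a CNN backbone
#'
#' Builds the named branch architecture with seeded random (He) weight
#' initialization and a 2-class output head. The model exposes a forward
#' pass to class scores and a tap hook returning the flattened tap-layer
#' output (see [backbone_registry()] for the printed tap sizes).
#' ImageNet-pretrained initialization is not bundled; `pretrained = TRUE`
#' raises an error.
#'
#' @param name backbone name (see [backbone_registry()]).
#' @param seed seed of the weight initialization.
#' @param pretrained must be `FALSE`.
#' @return an initialized `cnn_model`.
#' @export
build_backbone <- function(name, seed = 1L, pretrained = FALSE) {
  if (isTRUE(pretrained))
    stopf("pretrained ImageNet weights are not bundled; use pretrained = FALSE")
  builder <- switch(name,
    squeezenet = build_squeezenet, googlenet = build_googlenet,
    googlenet_v1 = build_googlenet_v1, resnet18 = build_resnet18,
    vgg16 = build_vgg16, densenet201 = build_densenet201, tiny = build_tiny,
    stopf("unknown backbone '%s'", name))
  nn_init(builder(), seed = seed)
}

# --- data adaptation --------------------------------------------------------

# single-modality patches -> input tensor at the model's native size.
# Patches are bilinearly resized, scaled to [-0.5, 0.5], and replicated to
# the model's channel count.
patches_to_input <- function(model, patches, channel = c("bmode", "ceus", "fused")) {
  channel <- match.arg(channel)
  a <- if (channel == "fused") patches$fused else patches[[channel]]
  n <- dim(a)[3]
  h <- model$input$h; w <- model$input$w; cc <- model$input$c
  d <- matrix(0, n * h * w, cc)
  for (i in seq_len(n)) {
    m <- bilinear_resize(a[, , i], h, w) / 255 - 0.5
    d[(i - 1L) * h * w + seq_len(h * w), ] <- as.vector(m)
  }
  tnsr(d, h, w, cc, n)
}

labels_to_onehot <- function(y) {
  y <- factor(as.character(y), levels = c("HCC", "PAR"))
  cbind(HCC = as.numeric(y == "HCC"), PAR = as.numeric(y == "PAR"))
}

#' Branch training configuration
#'
#' Defaults follow the published fine-tuning schedule: stochastic gradient
#' descent with momentum, learning rate 0.0002, momentum 0.1, minibatch 25,
#' 70 epochs, with train-time flip/translation augmentation. When training
#' the small `tiny` backbone from random initialization, a larger learning
#' rate (around 0.01) and fewer epochs are appropriate; see the package
#' vignette.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum momentum coefficient.
#' @param minibatch minibatch size.
#' @param epochs training epochs.
#' @param seed seed controlling shuffling and augmentation.
#' @param augmentation apply [train_time_augment()] each epoch.
#' @param pretrained must be FALSE (no bundled weights).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, momentum = 0.1,
                         minibatch = 25L, epochs = 70L, seed = 1L,
                         augmentation = TRUE, pretrained = FALSE) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            is_count(minibatch), is_count(epochs))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 minibatch = as.integer(minibatch), epochs = as.integer(epochs),
                 seed = as.integer(seed), augmentation = isTRUE(augmentation),
                 pretrained = isTRUE(pretrained)),
            class = "train_config")
}

#' Train a CNN branch on one modality
#'
#' Minimizes the 2-class cross-entropy with stochastic gradient descent with
#' momentum (`v <- momentum * v - lr * grad; w <- w + v`), shuffling each
#' epoch and optionally re-augmenting the training patches with random
#' flips/translations. Deterministic given `config$seed` (single-threaded
#' kernels assumed; same-platform reproducibility).
#'
#' @param model a `cnn_model` from [build_backbone()].
#' @param patches a [paired_patches()] training collection (both classes
#'   required).
#' @param channel `"bmode"`, `"ceus"`, or `"fused"` (a collection carrying a
#'   `fused` array, see [fuse_patches()]).
#' @param config a [train_config()].
#' @return the trained model, with a `history` data frame (per-epoch mean
#'   loss and training accuracy) attached.
#' @export
train_branch <- function(model, patches, channel = "bmode",
                         config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  y <- labels_to_onehot(patches$label)
  if (length(unique(patches$label)) < 2)
    stopf("training data must contain both classes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- length(patches)
  vel <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    pp <- if (config$augmentation) train_time_augment(patches) else patches
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = config$minibatch)) {
      idx <- ord[start:min(start + config$minibatch - 1L, n)]
      xb <- patches_to_input(model, pp[idx], channel)
      yb <- y[idx, , drop = FALSE]
      cache <- new.env(parent = emptyenv())
      vals <- nn_forward(model, xb, cache = cache)
      p <- get("softmax", envir = vals)$data
      m <- nrow(yb)
      ep_loss <- ep_loss - sum(log(pmax(rowSums(p * yb), 1e-12)))
      ep_correct <- ep_correct + sum(max.col(p) == max.col(yb))
      dlogits <- (p - yb) / m
      grads <- nn_backward(model, vals, cache, "softmax", dlogits)
      for (nm in names(grads)) {
        for (par in c("W", "b")) {
          key <- paste0(nm, ".", par)
          g <- grads[[nm]][[par]]
          v <- if (is.null(vel[[key]])) -config$learning_rate * g
               else config$momentum * vel[[key]] - config$learning_rate * g
          vel[[key]] <- v
          model$nodes[[nm]][[par]] <- model$nodes[[nm]][[par]] + v
        }
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n, acc = ep_correct / n))
  }
  model$history <- history
  model
}

#' Extract tap-layer feature vectors
#'
#' Runs the forward pass and returns the flattened tap-layer output per
#' patch, order-preserving. Passing several tap names (e.g. SqueezeNet's
#' `c("relu_conv10", "pool10")`) concatenates their flattened outputs.
#'
#' @param model a `cnn_model`.
#' @param patches a [paired_patches()] collection.
#' @param channel modality to feed.
#' @param tap tap layer name(s); defaults to the model's registered tap.
#' @return numeric matrix, one row per patch.
#' @export
extract_features <- function(model, patches, channel = "bmode",
                             tap = model$tap) {
  x <- patches_to_input(model, patches, channel)
  vals <- nn_forward(model, x, upto = tap)
  do.call(cbind, lapply(tap, function(nm) tensor_flat(get(nm, envir = vals))))
}

#' Class probabilities of a CNN branch
#'
#' @param model a (trained) `cnn_model`.
#' @param patches a [paired_patches()] collection.
#' @param channel modality to feed.
#' @return a [class_probabilities()] matrix (softmax outputs).
#' @export
predict_probabilities <- function(model, patches, channel = "bmode") {
  x <- patches_to_input(model, patches, channel)
  vals <- nn_forward(model, x, upto = "softmax")
  p <- get("softmax", envir = vals)$data
  class_probabilities(p[, 1], p[, 2])
}

#' Render a feature vector as a grayscale activation map
#'
#' Reshapes a tap-layer feature vector into a `target_shape` image
#' (row-major fill) and min--max normalizes it to \[0, 255\]; a constant
#' vector maps to the all-zero image.
#'
#' @param v numeric feature vector.
#' @param target_shape integer `c(rows, cols)` with
#'   `prod(target_shape) == length(v)`.
#' @return a `rows x cols` numeric matrix in \[0, 255\].
#' @export
activation_map <- function(v, target_shape) {
  stopifnot(length(target_shape) == 2)
  if (prod(target_shape) != length(v))
    stopf("target_shape %dx%d does not match vector length %d",
          target_shape[1], target_shape[2], length(v))
  m <- matrix(v, target_shape[1], target_shape[2], byrow = TRUE)
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, target_shape[1], target_shape[2]))
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Attach a fused image channel to a patch collection
#'
#' Applies [fuse_images()] to every pair and stores the result as a `fused`
#' array usable as `channel = "fused"` in the training and prediction
#' functions (feature-level fusion).
#'
#' @param patches a [paired_patches()] collection.
#' @param method,weights see [fuse_images()].
#' @return the collection with a `fused` array added.
#' @export
fuse_patches <- function(patches, method = "arithmetic_mean", weights = c(2, 1)) {
  stopifnot(inherits(patches, "paired_patches"))
  patches$fused <- fuse_images(patches$bmode, patches$ceus, method, weights)
  patches$fuse_spec <- list(method = method, weights = weights)
  patches
}
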