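# ---------------------------------------------------------------------------
# Compact CNN engine.
#
# Tensors are lists (h, w, c, n, data) where data is an (n*h*w) x c matrix;
# pixel order within an image is column-major (row fastest), images stacked.
# A model is a DAG of named nodes evaluated in definition order; supported
# ops: conv (+ optional fused relu), relu, maxpool/avgpool (optional
# ceil-mode output size with asymmetric right/bottom padding), gap (global
# average pool), fc (on the flattened tensor), concat (channels), add,
# softmax. Convolution is im2col + BLAS matrix multiplication; gather/scatter
# index maps are cached per node since shapes are fixed per model.
# Backpropagation covers every op, so any model built from these primitives
# is trainable with SGD-with-momentum on the cross-entropy loss.
# ---------------------------------------------------------------------------

tnsr <- function(data, h, w, c, n) list(data = data, h = h, w = w, c = c, n = n)

tensor_flat <- function(x) {
  # n x (h*w*c) matrix; feature index = (channel-1)*h*w + position
  n <- x$n; hw <- x$h * x$w
  out <- matrix(0, n, hw * x$c)
  for (ch in seq_len(x$c))
    out[, (ch - 1L) * hw + seq_len(hw)] <- matrix(x$data[, ch], n, hw, byrow = TRUE)[, , drop = FALSE]
  out
}

pad_indices <- function(h, w, n, pt, pb, pl, pr) {
  ph <- h + pt + pb; pw <- w + pl + pr
  pos <- 0:(h * w - 1L)
  r <- pos %% h + 1L
  cc <- pos %/% h + 1L
  tgt <- (cc + pl - 1L) * ph + (r + pt)
  idx <- rep(tgt, n) + rep((seq_len(n) - 1L) * ph * pw, each = h * w)
  list(idx = idx, ph = ph, pw = pw)
}

pad_data <- function(x, pt, pb, pl, pr, fill = 0) {
  if (pt == 0 && pb == 0 && pl == 0 && pr == 0) return(x)
  pi <- pad_indices(x$h, x$w, x$n, pt, pb, pl, pr)
  d <- matrix(fill, x$n * pi$ph * pi$pw, x$c)
  d[pi$idx, ] <- x$data
  tnsr(d, pi$ph, pi$pw, x$c, x$n)
}

im2col_idx <- function(ph, pw, oh, ow, k, s, n) {
  orv <- rep(seq_len(oh), times = ow)
  ocv <- rep(seq_len(ow), each = oh)
  base_r <- (orv - 1L) * s
  base_c <- (ocv - 1L) * s
  M <- matrix(0L, oh * ow, k * k)
  q <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    q <- q + 1L
    M[, q] <- (base_c + kj - 1L) * ph + base_r + ki
  }
  if (n > 1L) {
    M <- M[rep(seq_len(oh * ow), n), , drop = FALSE] +
      rep((seq_len(n) - 1L) * ph * pw, each = oh * ow)
  }
  M
}

out_size <- function(h, k, s, p, ceil_mode = FALSE) {
  o <- (h + 2 * p - k) / s + 1
  o <- if (ceil_mode) ceiling(o) else floor(o)
  extra <- (o - 1L) * s + k - (h + 2L * p)
  list(o = as.integer(o), extra = max(0L, as.integer(extra)))
}

# --- node constructors ------------------------------------------------------

nd_conv <- function(name, input, k, cout, stride = 1L, pad = 0L, act = "none") {
  list(name = name, op = "conv", inputs = input, k = as.integer(k),
       cout = as.integer(cout), stride = as.integer(stride),
       pad = as.integer(pad), act = act)
}
nd_pool <- function(name, input, type, k, stride, pad = 0L, ceil_mode = FALSE) {
  list(name = name, op = "pool", inputs = input, type = type,
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       ceil_mode = ceil_mode)
}
nd_gap <- function(name, input) list(name = name, op = "gap", inputs = input)
nd_fc <- function(name, input, cout, act = "none")
  list(name = name, op = "fc", inputs = input, cout = as.integer(cout), act = act)
nd_concat <- function(name, inputs) list(name = name, op = "concat", inputs = inputs)
nd_add <- function(name, inputs) list(name = name, op = "add", inputs = inputs)
nd_relu <- function(name, input) list(name = name, op = "relu", inputs = input)
nd_softmax <- function(name, input) list(name = name, op = "softmax", inputs = input)

# --- model assembly and initialization -------------------------------------

nn_model <- function(name, input, nodes, tap, classifier) {
  nms <- vapply(nodes, `[[`, "", "name")
  names(nodes) <- nms
  structure(list(name = name, input = input, nodes = nodes, tap = tap,
                 classifier = classifier, env = new.env(parent = emptyenv())),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s: %d nodes, input %dx%dx%d, tap '%s'\n",
              x$name, length(x$nodes), x$input$h, x$input$w, x$input$c,
              paste(x$tap, collapse = "+")))
  invisible(x)
}

# walk the graph once to infer shapes and allocate He-initialized weights
nn_init <- function(model, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shapes <- list(.input = model$input)
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    ins <- lapply(nd$inputs, function(nm)
      if (nm == ".input") shapes$.input else shapes[[nm]])
    s1 <- ins[[1]]
    sh <- switch(nd$op,
      conv = {
        os_h <- out_size(s1$h, nd$k, nd$stride, nd$pad)
        os_w <- out_size(s1$w, nd$k, nd$stride, nd$pad)
        fan_in <- nd$k^2 * s1$c
        model$nodes[[i]]$W <- matrix(stats::rnorm(fan_in * nd$cout,
                                                  sd = sqrt(2 / fan_in)),
                                     fan_in, nd$cout)
        model$nodes[[i]]$b <- numeric(nd$cout)
        list(h = os_h$o, w = os_w$o, c = nd$cout)
      },
      pool = {
        os_h <- out_size(s1$h, nd$k, nd$stride, nd$pad, nd$ceil_mode)
        os_w <- out_size(s1$w, nd$k, nd$stride, nd$pad, nd$ceil_mode)
        list(h = os_h$o, w = os_w$o, c = s1$c)
      },
      gap = list(h = 1L, w = 1L, c = s1$c),
      fc = {
        fan_in <- s1$h * s1$w * s1$c
        # classifier/projection layers start small so an untrained model
        # sits near chance-level cross-entropy
        model$nodes[[i]]$W <- matrix(stats::rnorm(fan_in * nd$cout,
                                                  sd = sqrt(0.5 / fan_in)),
                                     fan_in, nd$cout)
        model$nodes[[i]]$b <- numeric(nd$cout)
        list(h = 1L, w = 1L, c = nd$cout)
      },
      concat = list(h = s1$h, w = s1$w,
                    c = sum(vapply(ins, function(s) s$c, 0L))),
      add = s1,
      relu = s1,
      softmax = s1,
      stopf("unknown op '%s'", nd$op))
    shapes[[nd$name]] <- sh
  }
  model$shapes <- shapes
  model
}

node_shape <- function(model, name)
  if (name == ".input") model$input else model$shapes[[name]]

# cached gather indices for conv/pool nodes (shapes fixed per model)
node_idx <- function(model, nd, s1, n) {
  key <- paste0(nd$name, ":", n)
  cached <- model$env[[key]]
  if (!is.null(cached)) return(cached)
  ceil_mode <- isTRUE(nd$ceil_mode)
  os_h <- out_size(s1$h, nd$k, nd$stride, nd$pad, ceil_mode)
  os_w <- out_size(s1$w, nd$k, nd$stride, nd$pad, ceil_mode)
  pt <- nd$pad; pl <- nd$pad
  pb <- nd$pad + os_h$extra; pr <- nd$pad + os_w$extra
  ph <- s1$h + pt + pb; pw <- s1$w + pl + pr
  IDX <- im2col_idx(ph, pw, os_h$o, os_w$o, nd$k, nd$stride, n)
  val <- list(IDX = IDX, pt = pt, pb = pb, pl = pl, pr = pr,
              oh = os_h$o, ow = os_w$o, ph = ph, pw = pw)
  model$env[[key]] <- val
  val
}

# --- forward ----------------------------------------------------------------

fwd_conv <- function(model, nd, x, cache) {
  if (nd$k == 1L && nd$stride == 1L && nd$pad == 0L) {
    X2 <- x$data
    oh <- x$h; ow <- x$w
  } else {
    ii <- node_idx(model, nd, x, x$n)
    xp <- pad_data(x, ii$pt, ii$pb, ii$pl, ii$pr, fill = 0)
    k2 <- nd$k^2
    X2 <- matrix(0, nrow(ii$IDX), k2 * x$c)
    for (ch in seq_len(x$c))
      X2[, (ch - 1L) * k2 + seq_len(k2)] <- xp$data[, ch][ii$IDX]
    oh <- ii$oh; ow <- ii$ow
  }
  Y <- X2 %*% nd$W
  Y <- sweep(Y, 2, nd$b, "+")
  if (nd$act == "relu") Y <- pmax(Y, 0)
  out <- tnsr(Y, oh, ow, nd$cout, x$n)
  if (!is.null(cache)) cache[[nd$name]] <- list(X2 = X2, Y = Y, x_c = x$c)
  out
}

fwd_pool <- function(model, nd, x, cache) {
  ii <- node_idx(model, nd, x, x$n)
  fill <- if (nd$type == "max") -Inf else 0
  if (nd$type == "avg" && (ii$pt > 0 || ii$pb > 0 || ii$pl > 0 || ii$pr > 0))
    stopf("average pooling with padding is not supported")
  xp <- pad_data(x, ii$pt, ii$pb, ii$pl, ii$pr, fill = fill)
  m <- nrow(ii$IDX)
  Y <- matrix(0, m, x$c)
  AM <- if (nd$type == "max") matrix(0L, m, x$c)
  for (ch in seq_len(x$c)) {
    Xw <- matrix(xp$data[, ch][ii$IDX], m)
    if (nd$type == "max") {
      am <- max.col(Xw, ties.method = "first")
      AM[, ch] <- am
      Y[, ch] <- Xw[cbind(seq_len(m), am)]
    } else {
      Y[, ch] <- rowMeans(Xw)
    }
  }
  if (!is.null(cache)) cache[[nd$name]] <- list(AM = AM)
  tnsr(Y, ii$oh, ii$ow, x$c, x$n)
}

fwd_gap <- function(nd, x) {
  grp <- rep(seq_len(x$n), each = x$h * x$w)
  Y <- rowsum(x$data, grp, reorder = TRUE) / (x$h * x$w)
  tnsr(Y, 1L, 1L, x$c, x$n)
}

fwd_fc <- function(nd, x, cache) {
  Xf <- tensor_flat(x)
  Y <- sweep(Xf %*% nd$W, 2, nd$b, "+")
  if (nd$act == "relu") Y <- pmax(Y, 0)
  if (!is.null(cache)) cache[[nd$name]] <- list(Xf = Xf, Y = Y)
  tnsr(Y, 1L, 1L, nd$cout, x$n)
}

nn_forward <- function(model, x, upto = NULL, cache = NULL) {
  vals <- new.env(parent = emptyenv())
  assign(".input", x, envir = vals)
  need <- if (is.null(upto)) names(model$nodes) else upto
  remaining <- length(need)
  for (nd in model$nodes) {
    ins <- lapply(nd$inputs, function(nm) get(nm, envir = vals))
    x1 <- ins[[1]]
    out <- switch(nd$op,
      conv = fwd_conv(model, nd, x1, cache),
      pool = fwd_pool(model, nd, x1, cache),
      gap = fwd_gap(nd, x1),
      fc = fwd_fc(nd, x1, cache),
      relu = tnsr(pmax(x1$data, 0), x1$h, x1$w, x1$c, x1$n),
      concat = tnsr(do.call(cbind, lapply(ins, `[[`, "data")),
                    x1$h, x1$w, sum(vapply(ins, `[[`, 0L, "c")), x1$n),
      add = {
        d <- ins[[1]]$data
        for (j in seq_along(ins)[-1]) d <- d + ins[[j]]$data
        tnsr(d, x1$h, x1$w, x1$c, x1$n)
      },
      softmax = {
        z <- x1$data - apply(x1$data, 1, max)
        e <- exp(z)
        tnsr(e / rowSums(e), x1$h, x1$w, x1$c, x1$n)
      })
    assign(nd$name, out, envir = vals)
    if (nd$name %in% need) {
      remaining <- remaining - 1L
      if (remaining == 0L) break
    }
  }
  vals
}

# --- backward ---------------------------------------------------------------

bwd_conv <- function(model, nd, x, dY, cc) {
  if (nd$act == "relu") dY <- dY * (cc$Y > 0)
  grads <- list(W = crossprod(cc$X2, dY), b = colSums(dY))
  dX2 <- dY %*% t(nd$W)
  if (nd$k == 1L && nd$stride == 1L && nd$pad == 0L) {
    dX <- dX2
  } else {
    ii <- node_idx(model, nd, x, x$n)
    k2 <- nd$k^2
    dpad <- matrix(0, x$n * ii$ph * ii$pw, x$c)
    for (ch in seq_len(x$c)) {
      acc <- numeric(x$n * ii$ph * ii$pw)
      for (q in seq_len(k2)) {
        iq <- ii$IDX[, q]
        acc[iq] <- acc[iq] + dX2[, (ch - 1L) * k2 + q]
      }
      dpad[, ch] <- acc
    }
    pi <- pad_indices(x$h, x$w, x$n, ii$pt, ii$pb, ii$pl, ii$pr)
    dX <- dpad[pi$idx, , drop = FALSE]
  }
  list(dX = tnsr(dX, x$h, x$w, x$c, x$n), grads = grads)
}

bwd_pool <- function(model, nd, x, dY, cc) {
  ii <- node_idx(model, nd, x, x$n)
  m <- nrow(ii$IDX); k2 <- nd$k^2
  dpad <- matrix(0, x$n * ii$ph * ii$pw, x$c)
  for (ch in seq_len(x$c)) {
    acc <- numeric(x$n * ii$ph * ii$pw)
    if (nd$type == "max") {
      am <- cc$AM[, ch]
      for (q in seq_len(k2)) {
        sel <- which(am == q)
        if (!length(sel)) next
        iq <- ii$IDX[sel, q]
        acc[iq] <- acc[iq] + dY[sel, ch]
      }
    } else {
      for (q in seq_len(k2)) {
        iq <- ii$IDX[, q]
        acc[iq] <- acc[iq] + dY[, ch] / k2
      }
    }
    dpad[, ch] <- acc
  }
  pi <- pad_indices(x$h, x$w, x$n, ii$pt, ii$pb, ii$pl, ii$pr)
  tnsr(dpad[pi$idx, , drop = FALSE], x$h, x$w, x$c, x$n)
}

bwd_fc <- function(nd, x, dY, cc) {
  if (nd$act == "relu") dY <- dY * (cc$Y > 0)
  grads <- list(W = crossprod(cc$Xf, dY), b = colSums(dY))
  dXf <- dY %*% t(nd$W)
  hw <- x$h * x$w
  dX <- matrix(0, x$n * hw, x$c)
  for (ch in seq_len(x$c))
    dX[, ch] <- as.vector(t(dXf[, (ch - 1L) * hw + seq_len(hw), drop = FALSE]))
  list(dX = tnsr(dX, x$h, x$w, x$c, x$n), grads = grads)
}

# backward pass from d(final node data); returns per-node parameter grads
nn_backward <- function(model, vals, cache, final, dFinal) {
  dts <- new.env(parent = emptyenv())
  assign(final, dFinal, envir = dts)
  grads <- list()
  node_names <- names(model$nodes)
  i_final <- match(final, node_names)
  for (i in rev(seq_len(i_final))) {
    nd <- model$nodes[[i]]
    if (is.null(dts[[nd$name]])) next
    dY <- dts[[nd$name]]
    x1 <- get(nd$inputs[[1]], envir = vals)
    push <- function(nm, d) {
      cur <- dts[[nm]]
      assign(nm, if (is.null(cur)) d else cur + d, envir = dts)
    }
    switch(nd$op,
      conv = {
        r <- bwd_conv(model, nd, x1, dY, cache[[nd$name]])
        grads[[nd$name]] <- r$grads
        push(nd$inputs[[1]], r$dX$data)
      },
      pool = push(nd$inputs[[1]],
                  bwd_pool(model, nd, x1, dY, cache[[nd$name]])$data),
      gap = {
        hw <- x1$h * x1$w
        push(nd$inputs[[1]], (dY / hw)[rep(seq_len(x1$n), each = hw), , drop = FALSE])
      },
      fc = {
        r <- bwd_fc(nd, x1, dY, cache[[nd$name]])
        grads[[nd$name]] <- r$grads
        push(nd$inputs[[1]], r$dX$data)
      },
      relu = push(nd$inputs[[1]], dY * (x1$data > 0)),
      concat = {
        off <- 0L
        for (nm in nd$inputs) {
          cc1 <- get(nm, envir = vals)$c
          push(nm, dY[, off + seq_len(cc1), drop = FALSE])
          off <- off + cc1
        }
      },
      add = for (nm in nd$inputs) push(nm, dY),
      softmax = push(nd$inputs[[1]], dY))  # dY already w.r.t. logits
  }
  grads
}
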