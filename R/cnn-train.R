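# A small, self-contained CNN training engine executing melascan_arch
# specifications: im2col-based convolution, max pooling, dense layers,
# dropout, softmax cross-entropy, and Adam. Written for the modest network
# sizes this toolkit trains (the designed two-conv network); it is not a
# general deep-learning framework. Also provides Grad-CAM on the trained
# model.

# Precompute im2col linear indices into the zero-padded input array for a
# conv (per-sample, all channels) or pooling (single-channel) layer.
im2col_index <- function(h, w, ch, kh, kw, stride, padding) {
  if (padding == "same") {
    oh <- ceiling(h / stride); ow <- ceiling(w / stride)
    ph <- max((oh - 1) * stride + kh - h, 0)
    pw <- max((ow - 1) * stride + kw - w, 0)
    pt <- ph %/% 2L; pl <- pw %/% 2L
  } else {
    oh <- floor((h - kh) / stride) + 1L; ow <- floor((w - kw) / stride) + 1L
    pt <- 0L; pl <- 0L; ph <- 0L; pw <- 0L
  }
  hp <- h + ph; wp <- w + pw
  r0 <- (seq_len(oh) - 1L) * stride + 1L          # top row of each patch
  c0 <- (seq_len(ow) - 1L) * stride + 1L
  # output positions in column-major order (oh fastest), matching array layout
  pos_r <- rep(r0, times = ow)
  pos_c <- rep(c0, each = oh)
  npos <- oh * ow
  off <- expand.grid(dr = 0:(kh - 1L), dc = 0:(kw - 1L), dk = 0:(ch - 1L))
  idx <- matrix(0L, npos, nrow(off))
  for (j in seq_len(nrow(off))) {
    idx[, j] <- (pos_r + off$dr[j]) + (pos_c + off$dc[j] - 1L) * hp +
      off$dk[j] * hp * wp
  }
  list(idx = idx, oh = oh, ow = ow, hp = hp, wp = wp, pt = pt, pl = pl,
       h = h, w = w, ch = ch)
}

pad_input <- function(x, geo) {
  if (geo$hp == geo$h && geo$wp == geo$w) return(x)
  xp <- array(0, dim = c(geo$hp, geo$wp, geo$ch))
  xp[geo$pt + seq_len(geo$h), geo$pl + seq_len(geo$w), ] <- x
  xp
}

unpad_grad <- function(dxp, geo) {
  if (geo$hp == geo$h && geo$wp == geo$w) return(dxp)
  dxp[geo$pt + seq_len(geo$h), geo$pl + seq_len(geo$w), , drop = FALSE]
}

#' Initialise trainable weights for an architecture
#'
#' He-normal weights, zero biases; layer geometry (im2col indices) is
#' precomputed for the spec's fixed input shape.
#'
#' @param spec a `melascan_arch`.
#' @param seed integer RNG seed.
#' @return object of class `melascan_cnn`.
#' @export
cnn_init <- function(spec, seed = 0L) {
  set.seed(seed)
  shapes <- infer_shapes(spec)
  in_shape <- function(i) if (i == 1L) spec$input_shape else shapes[[i - 1L]]
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    st <- list(def = l)
    ins <- in_shape(i)
    if (l$kind == "conv") {
      st$geo <- im2col_index(ins[1], ins[2], ins[3], l$kernel[1], l$kernel[2],
                             l$stride, l$padding)
      fan_in <- l$kernel[1] * l$kernel[2] * ins[3]
      st$W <- matrix(stats::rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                     fan_in, l$filters)
      st$b <- numeric(l$filters)
    } else if (l$kind == "maxpool") {
      st$geo <- im2col_index(ins[1], ins[2], 1L, l$kernel[1], l$kernel[2],
                             l$stride, l$padding)
      st$channels <- ins[3]
    } else if (l$kind == "dense") {
      fan_in <- prod(ins)
      st$W <- matrix(stats::rnorm(fan_in * l$units, sd = sqrt(2 / fan_in)),
                     fan_in, l$units)
      st$b <- numeric(l$units)
    }
    layers[[i]] <- st
  }
  structure(list(spec = spec, layers = layers, shapes = shapes),
            class = "melascan_cnn")
}

apply_activation <- function(x, name) {
  switch(name,
    relu = pmax(x, 0),
    tanh = tanh(x),
    linear = x,
    softmax = { e <- exp(x - max(x)); e / sum(e) },
    stop("unknown activation: ", name, call. = FALSE))
}

activation_grad <- function(dout, out, name) {
  switch(name,
    relu = dout * (out > 0),
    tanh = dout * (1 - out^2),
    linear = dout,
    stop("cannot backpropagate through activation: ", name, call. = FALSE))
}

# Forward pass for one sample. Returns per-layer outputs and caches; the
# final dense layer's softmax is kept separate so that gradients start at
# the logits. `train` enables dropout (with RNG) using inverted scaling.
cnn_forward <- function(model, x, train = FALSE) {
  outs <- vector("list", length(model$layers))
  caches <- vector("list", length(model$layers))
  cur <- x
  for (i in seq_along(model$layers)) {
    st <- model$layers[[i]]
    l <- st$def
    if (l$kind == "rescale") {
      cur <- cur * l$scale
    } else if (l$kind == "conv") {
      geo <- st$geo
      xp <- pad_input(cur, geo)
      patches <- matrix(xp[geo$idx], nrow(geo$idx))
      z <- sweep(patches %*% st$W, 2, st$b, "+")
      caches[[i]] <- list(patches = patches)
      cur <- array(z, dim = c(geo$oh, geo$ow, l$filters))
      if (!is.null(l$activation) && l$activation != "softmax")
        cur <- apply_activation(cur, l$activation)
    } else if (l$kind == "maxpool") {
      geo <- st$geo
      out <- array(0, dim = c(geo$oh, geo$ow, st$channels))
      amax <- matrix(0L, nrow(geo$idx), st$channels)
      for (k in seq_len(st$channels)) {
        xc <- cur[, , k]
        patches <- matrix(xc[geo$idx], nrow(geo$idx))
        am <- max.col(patches, ties.method = "first")
        amax[, k] <- geo$idx[cbind(seq_len(nrow(patches)), am)]
        out[, , k] <- patches[cbind(seq_len(nrow(patches)), am)]
      }
      caches[[i]] <- list(amax = amax)
      cur <- out
    } else if (l$kind == "activation") {
      cur <- apply_activation(cur, l$activation)
    } else if (l$kind == "flatten") {
      caches[[i]] <- list(shape = dim(cur))
      cur <- as.vector(cur)
    } else if (l$kind == "dense") {
      xin <- as.vector(cur)
      caches[[i]] <- list(x = xin)
      z <- as.vector(crossprod(st$W, xin)) + st$b
      act <- l$activation
      if (!is.null(act) && act != "softmax") z <- apply_activation(z, act)
      cur <- z
    } else if (l$kind == "dropout") {
      if (train) {
        keep <- stats::runif(length(cur)) >= l$rate
        cur <- cur * keep / (1 - l$rate)
        caches[[i]] <- list(keep = keep)
      }
    }
    outs[[i]] <- cur
  }
  logits <- outs[[length(outs)]]
  list(outs = outs, caches = caches, logits = logits,
       probs = apply_activation(logits, "softmax"))
}

# Backward pass from d(loss)/d(logits) down to layer `stop_at` (exclusive);
# returns gradients for W/b per layer and, if stop_at > 0, the gradient at
# the output of layer `stop_at`.
cnn_backward <- function(model, fwd, dlogits, train = FALSE, stop_at = 0L) {
  n <- length(model$layers)
  grads <- vector("list", n)
  cur <- dlogits
  input_of <- function(i) if (i == 1L) NULL else fwd$outs[[i - 1L]]
  for (i in rev(seq_len(n))) {
    if (i == stop_at) return(list(grads = grads, d_at_stop = cur))
    st <- model$layers[[i]]
    l <- st$def
    if (l$kind == "rescale") {
      cur <- cur * l$scale
    } else if (l$kind == "dense") {
      act <- l$activation
      if (!is.null(act) && act != "softmax")
        cur <- activation_grad(cur, fwd$outs[[i]], act)
      xin <- fwd$caches[[i]]$x
      grads[[i]] <- list(dW = outer(xin, cur), db = cur)
      cur <- as.vector(st$W %*% cur)
    } else if (l$kind == "dropout") {
      if (train && !is.null(fwd$caches[[i]]))
        cur <- cur * fwd$caches[[i]]$keep / (1 - l$rate)
    } else if (l$kind == "flatten") {
      cur <- array(cur, dim = fwd$caches[[i]]$shape)
    } else if (l$kind == "activation") {
      cur <- activation_grad(cur, fwd$outs[[i]], l$activation)
    } else if (l$kind == "maxpool") {
      geo <- st$geo
      amax <- fwd$caches[[i]]$amax
      dx <- array(0, dim = dim(input_of(i)))
      plane <- geo$hp * geo$wp
      for (k in seq_len(st$channels)) {
        dc <- array(0, dim = c(geo$hp, geo$wp))
        dcur_k <- as.vector(cur[, , k])
        # accumulate: several output cells may share an argmax when patches overlap
        acc <- rowsum(dcur_k, group = amax[, k])
        dc[as.integer(rownames(acc))] <- acc
        dx[, , k] <- unpad_grad(array(dc, dim = c(geo$hp, geo$wp, 1L)),
                                geo)[, , 1L]
      }
      cur <- dx
    } else if (l$kind == "conv") {
      act <- l$activation
      if (!is.null(act) && act != "softmax")
        cur <- activation_grad(cur, fwd$outs[[i]], act)
      geo <- st$geo
      dmat <- matrix(cur, nrow(geo$idx), l$filters)
      patches <- fwd$caches[[i]]$patches
      grads[[i]] <- list(dW = crossprod(patches, dmat), db = colSums(dmat))
      dpatches <- dmat %*% t(st$W)
      dxp <- numeric(geo$hp * geo$wp * geo$ch)
      for (j in seq_len(ncol(geo$idx)))
        dxp[geo$idx[, j]] <- dxp[geo$idx[, j]] + dpatches[, j]
      cur <- unpad_grad(array(dxp, dim = c(geo$hp, geo$wp, geo$ch)), geo)
    }
  }
  list(grads = grads, d_at_stop = NULL)
}

as_sample_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[4]), function(i) x[, , , i, drop = TRUE]))
  stop("x must be a list of H x W x C arrays or a 4-d array", call. = FALSE)
}

conform_sample <- function(s, input_shape) {
  if (is.matrix(s)) s <- array(s, dim = c(dim(s), 1L))
  if (dim(s)[3] == 1L && input_shape[3] == 3L)
    s <- array(rep(s, 3L), dim = c(dim(s)[1:2], 3L))
  if (!all(dim(s)[1:2] == input_shape[1:2]))
    s <- resize_to_shape(s, input_shape)
  s
}

resize_to_shape <- function(s, input_shape) {
  out <- array(0, dim = input_shape)
  for (k in seq_len(input_shape[3]))
    out[, , k] <- resize_image(s[, , min(k, dim(s)[3])], input_shape[1], input_shape[2])
  out
}

model_eval <- function(model, xs, ys) {
  loss <- 0; correct <- 0L
  for (i in seq_along(xs)) {
    fwd <- cnn_forward(model, xs[[i]], train = FALSE)
    p <- fwd$probs
    loss <- loss - log(max(p[ys[i]], 1e-12))
    correct <- correct + (which.max(p) == ys[i])
  }
  list(loss = loss / length(xs), accuracy = correct / length(xs))
}

augment_sample <- function(s, max_shift = 4L, max_angle = 15) {
  if (stats::runif(1) < 0.5) s <- s[, rev(seq_len(dim(s)[2])), , drop = FALSE]  # horizontal flip
  if (stats::runif(1) < 0.5) s <- s[rev(seq_len(dim(s)[1])), , , drop = FALSE]  # vertical flip
  dr <- sample(-max_shift:max_shift, 1L); dc <- sample(-max_shift:max_shift, 1L)
  if (dr != 0 || dc != 0)
    for (k in seq_len(dim(s)[3])) s[, , k] <- shift_mat(s[, , k], dr, dc)
  ang <- stats::runif(1, -max_angle, max_angle)
  if (abs(ang) > 1) {
    for (k in seq_len(dim(s)[3])) {
      e <- EBImage::rotate(ebi(s[, , k]), ang,
                           output.dim = dim(s)[1:2], bg.col = mean(s[, , k]) / 255)
      s[, , k] <- unebi(e)
    }
  }
  s
}

#' Train a CNN on in-memory images
#'
#' Mini-batch Adam on softmax cross-entropy, following the training recipe
#' batch size 32, learning rate 1e-4. Deterministic for a fixed seed.
#'
#' @param spec a `melascan_arch`.
#' @param x list of H x W x C arrays (or an H x W x C x N array); grayscale
#'   samples are replicated to the spec's channel count and resized to its
#'   input shape if needed.
#' @param y class labels: factor, character, or integer indices 1..K.
#' @param epochs training epochs; 0 returns the initial weights and an empty
#'   history.
#' @param batch_size mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-4).
#' @param seed RNG seed governing initialisation, shuffling, dropout, and
#'   augmentation.
#' @param val_x,val_y optional validation set, evaluated each epoch.
#' @param augment apply random flips, shifts and small rotations to training
#'   samples (training split only).
#' @param model optionally continue training an existing `melascan_cnn`.
#' @param verbose print one line per epoch.
#' @return list with `model` (`melascan_cnn`), `history` (data.frame with
#'   epoch, loss, accuracy, and validation columns when a validation set is
#'   given), and `classes` (label ordering).
#' @export
cnn_train <- function(spec, x, y, epochs = 5L, batch_size = 32L, lr = 1e-4,
                      seed = 0L, val_x = NULL, val_y = NULL, augment = FALSE,
                      model = NULL, verbose = FALSE) {
  xs <- as_sample_list(x)
  if (is.factor(y) || is.character(y)) {
    classes <- sort(unique(as.character(y)))
    yi <- match(as.character(y), classes)
  } else {
    yi <- as.integer(y)
    classes <- as.character(seq_len(max(yi)))
  }
  if (length(xs) != length(yi)) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(yi)) < 2L) stop("need at least two classes", call. = FALSE)
  n_class <- length(classes)
  if (is.null(model)) model <- cnn_init(spec, seed = seed)
  set.seed(seed + 1L)
  xs <- lapply(xs, conform_sample, input_shape = spec$input_shape)
  if (!is.null(val_x)) {
    vxs <- lapply(as_sample_list(val_x), conform_sample, input_shape = spec$input_shape)
    vyi <- if (is.factor(val_y) || is.character(val_y)) match(as.character(val_y), classes)
           else as.integer(val_y)
  }
  # Adam state per trainable layer
  opt <- lapply(model$layers, function(st) {
    if (!is.null(st$W)) list(mW = st$W * 0, vW = st$W * 0,
                             mb = st$b * 0, vb = st$b * 0) else NULL
  })
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  hist <- list()
  n <- length(xs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      batch <- ord[b0:min(b0 + batch_size - 1L, n)]
      acc <- NULL
      for (s in batch) {
        xi <- xs[[s]]
        if (augment) xi <- augment_sample(xi)
        fwd <- cnn_forward(model, xi, train = TRUE)
        p <- fwd$probs
        ep_loss <- ep_loss - log(max(p[yi[s]], 1e-12))
        ep_correct <- ep_correct + (which.max(p) == yi[s])
        dlog <- p
        dlog[yi[s]] <- dlog[yi[s]] - 1
        bw <- cnn_backward(model, fwd, dlog / length(batch), train = TRUE)
        if (is.null(acc)) acc <- bw$grads
        else for (i in seq_along(acc)) {
          if (!is.null(bw$grads[[i]])) {
            acc[[i]]$dW <- acc[[i]]$dW + bw$grads[[i]]$dW
            acc[[i]]$db <- acc[[i]]$db + bw$grads[[i]]$db
          }
        }
      }
      step <- step + 1L
      for (i in seq_along(model$layers)) {
        if (is.null(acc[[i]])) next
        o <- opt[[i]]
        o$mW <- beta1 * o$mW + (1 - beta1) * acc[[i]]$dW
        o$vW <- beta2 * o$vW + (1 - beta2) * acc[[i]]$dW^2
        o$mb <- beta1 * o$mb + (1 - beta1) * acc[[i]]$db
        o$vb <- beta2 * o$vb + (1 - beta2) * acc[[i]]$db^2
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        model$layers[[i]]$W <- model$layers[[i]]$W -
          lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
        model$layers[[i]]$b <- model$layers[[i]]$b -
          lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
        opt[[i]] <- o
      }
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n)
    if (!is.null(val_x)) {
      ev <- model_eval(model, vxs, vyi)
      row$val_loss <- ev$loss; row$val_accuracy <- ev$accuracy
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f", ep, row$loss, row$accuracy))
  }
  history <- if (length(hist)) do.call(rbind, hist)
             else data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  list(model = model, history = history, classes = classes)
}

#' Predict class probabilities with a trained CNN
#'
#' @param object a `melascan_cnn`.
#' @param x list of samples or 4-d array (see [cnn_train()]).
#' @param ... unused.
#' @return N x K matrix of softmax probabilities (rows sum to 1).
#' @export
predict.melascan_cnn <- function(object, x, ...) {
  xs <- lapply(as_sample_list(x), conform_sample, input_shape = object$spec$input_shape)
  t(vapply(xs, function(s) cnn_forward(object, s)$probs,
           numeric(utils::tail(object$shapes, 1)[[1]])))
}

#' Train a CNN from a class-folder image dataset
#'
#' Expects `dir/train/<class>/*.png` (and optionally `dir/test/<class>`,
#' used as the validation set). Augmentation, when enabled, is applied to
#' the training split only.
#'
#' @param spec a `melascan_arch`.
#' @param dir dataset root.
#' @param ... passed to [cnn_train()].
#' @return as [cnn_train()].
#' @export
cnn_train_dir <- function(spec, dir, ...) {
  read_split <- function(split) {
    root <- file.path(dir, split)
    if (!dir.exists(root)) return(NULL)
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (length(classes) < 2L) stop("need at least two class folders in ", root, call. = FALSE)
    xs <- list(); ys <- character(0)
    for (cl in classes) {
      files <- sort(list.files(file.path(root, cl), pattern = "\\.(png|jpe?g)$",
                               full.names = TRUE, ignore.case = TRUE))
      if (length(files) == 0L) stop("empty class folder: ", file.path(root, cl), call. = FALSE)
      for (f in files) {
        img <- read_image(f)
        if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
        xs[[length(xs) + 1L]] <- img
        ys <- c(ys, cl)
      }
    }
    list(x = xs, y = ys)
  }
  tr <- read_split("train")
  if (is.null(tr)) stop("no train/ folder under ", dir, call. = FALSE)
  te <- read_split("test")
  cnn_train(spec, tr$x, tr$y, val_x = if (is.null(te)) NULL else te$x,
            val_y = if (is.null(te)) NULL else te$y, ...)
}

#' Grad-CAM heatmap
#'
#' Gradient-weighted class-activation map: the gradient of the target
#' class's logit with respect to the last convolutional layer's activation
#' maps is pooled spatially into per-channel weights; the heatmap is the
#' ReLU of the weighted sum of those maps, normalised to [0, 1] unless
#' identically zero.
#'
#' @param model a `melascan_cnn` with at least one conv layer.
#' @param x one input sample (H x W x C array or grayscale matrix).
#' @param class target class index (1-based).
#' @return H' x W' matrix in [0, 1] at the last conv layer's resolution.
#' @export
grad_cam <- function(model, x, class) {
  conv_idx <- which(vapply(model$layers, function(st) st$def$kind == "conv", logical(1)))
  if (length(conv_idx) == 0L) stop("model has no convolutional layer", call. = FALSE)
  last_conv <- max(conv_idx)
  # use the activation immediately following the conv when present
  target <- last_conv
  if (target < length(model$layers) &&
      model$layers[[target + 1L]]$def$kind == "activation")
    target <- target + 1L
  s <- conform_sample(if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x,
                      model$spec$input_shape)
  fwd <- cnn_forward(model, s, train = FALSE)
  n_class <- length(fwd$logits)
  if (class < 1L || class > n_class) stop("class index out of range", call. = FALSE)
  dlog <- numeric(n_class)
  dlog[class] <- 1
  bw <- cnn_backward(model, fwd, dlog, train = FALSE, stop_at = target)
  grad <- bw$d_at_stop                      # d logit / d activation maps
  a <- fwd$outs[[target]]
  w <- apply(grad, 3, mean)                 # spatial mean pooling
  cam <- matrix(0, dim(a)[1], dim(a)[2])
  for (k in seq_len(dim(a)[3])) cam <- cam + w[k] * a[, , k]
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}
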