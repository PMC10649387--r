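# Declarative CNN architectures with analytic shape and parameter
# verification. A spec is an ordered list of layer descriptions from which
# every intermediate output shape and trainable-parameter count is derived
# in closed form, with no deep-learning framework involved.

#' Layer constructors
#'
#' Building blocks for [architecture_spec()]: 2-D convolution, max pooling,
#' standalone activation, flatten, dense, dropout, and input rescaling.
#' Kernel/pool sizes may be a single integer (square) or `c(h, w)`.
#'
#' @param filters,units number of output channels / neurons.
#' @param kernel,pool spatial extent.
#' @param stride step; pooling defaults to its own size.
#' @param padding `"same"` (output ceiling(n/stride)) or `"valid"`.
#' @param activation activation name attached to the layer (`NULL` for
#'   linear).
#' @param name activation name for a standalone activation layer.
#' @param rate dropout probability.
#' @param scale multiplicative input rescaling factor.
#' @return a `LayerSpec` list.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv2d <- function(filters, kernel, stride = 1L, padding = c("valid", "same"),
                         activation = NULL) {
  list(kind = "conv", filters = as.integer(filters),
       kernel = rep(as.integer(kernel), length.out = 2L),
       stride = as.integer(stride), padding = match.arg(padding),
       activation = activation)
}

#' @rdname layers
#' @export
layer_maxpool <- function(pool = 2L, stride = pool, padding = "valid") {
  list(kind = "maxpool", kernel = rep(as.integer(pool), length.out = 2L),
       stride = as.integer(stride), padding = padding)
}

#' @rdname layers
#' @export
layer_activation <- function(name = "relu") list(kind = "activation", activation = name)

#' @rdname layers
#' @export
layer_flatten <- function() list(kind = "flatten")

#' @rdname layers
#' @export
layer_dense <- function(units, activation = NULL)
  list(kind = "dense", units = as.integer(units), activation = activation)

#' @rdname layers
#' @export
layer_dropout <- function(rate) list(kind = "dropout", rate = rate)

#' @rdname layers
#' @export
layer_rescale <- function(scale = 1 / 255) list(kind = "rescale", scale = scale)

#' Assemble an architecture specification
#'
#' @param name model name.
#' @param input_shape `c(H, W, C)` input dimensions.
#' @param layers ordered list of layer specs (see [layers]).
#' @return object of class `melascan_arch`.
#' @export
architecture_spec <- function(name, input_shape, layers) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers),
            class = "melascan_arch")
}

conv_out_dim <- function(n, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(n / stride))
  else as.integer(floor((n - k) / stride) + 1L)
}

#' Per-layer output shapes of an architecture
#'
#' Spatial sizes follow the usual conventions: `same` padding gives
#' ceiling(n/stride); `valid` gives floor((n-k)/stride)+1.
#'
#' @param spec a `melascan_arch`.
#' @return list of integer shape vectors, one per layer (in layer order).
#' @export
infer_shapes <- function(spec) {
  shape <- spec$input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    shape <- switch(l$kind,
      conv = {
        h <- conv_out_dim(shape[1], l$kernel[1], l$stride, l$padding)
        w <- conv_out_dim(shape[2], l$kernel[2], l$stride, l$padding)
        c(h, w, l$filters)
      },
      maxpool = {
        h <- conv_out_dim(shape[1], l$kernel[1], l$stride, l$padding)
        w <- conv_out_dim(shape[2], l$kernel[2], l$stride, l$padding)
        c(h, w, shape[3])
      },
      flatten = prod(shape),
      dense = l$units,
      shape  # activation, dropout, rescale preserve shape
    )
    if (any(shape < 1))
      stop("layer ", i, " (", l$kind, ") produces a nonpositive dimension", call. = FALSE)
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Trainable-parameter counts of an architecture
#'
#' conv: kh*kw*Cin*Cout + Cout; dense: n_in*units + units; all other layer
#' kinds contribute 0.
#'
#' @param spec a `melascan_arch`.
#' @return list with `per_layer` (integer vector, one entry per layer) and
#'   `total`.
#' @export
count_params <- function(spec) {
  shapes <- infer_shapes(spec)
  in_shape <- function(i) if (i == 1L) spec$input_shape else shapes[[i - 1L]]
  per <- vapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      cin <- in_shape(i)[3]
      l$kernel[1] * l$kernel[2] * cin * l$filters + l$filters
    } else if (l$kind == "dense") {
      prod(in_shape(i)) * l$units + l$units
    } else 0
  }, numeric(1))
  list(per_layer = per, total = sum(per))
}

#' @export
print.melascan_arch <- function(x, ...) {
  shapes <- infer_shapes(x)
  params <- count_params(x)
  cat(sprintf("Model: \"%s\"  (input %s)\n", x$name,
              paste(x$input_shape, collapse = " x ")))
  cat(sprintf("%-4s %-12s %-16s %s\n", "#", "Layer", "Output shape", "Params"))
  for (i in seq_along(x$layers)) {
    cat(sprintf("%-4d %-12s %-16s %s\n", i, x$layers[[i]]$kind,
                paste(shapes[[i]], collapse = "x"),
                format(params$per_layer[i], big.mark = ",")))
  }
  cat("Total params:", format(params$total, big.mark = ","), "\n")
  invisible(x)
}

#' The designed melanoma-classification CNN
#'
#' Sequential network: rescale 1/255; conv 3x3, 32 filters, stride 4, same
#' padding, ReLU; maxpool 2; conv 5x5, 64 filters, stride 2, valid, ReLU;
#' maxpool 2; flatten; dense 38 (ReLU); dropout 0.2; dense `classes` with
#' softmax. At the default 224 x 224 x 3 input the layer shapes are
#' 56x56x32, 28x28x32, 12x12x64, 6x6x64, 2304, 38, 3 with parameter counts
#' 896, 51,264, 87,590 and 117 (139,867 total). The two convolution
#' kernel/stride settings are the unique small-integer configuration
#' producing exactly those shapes and counts.
#'
#' @param input_shape input dimensions `c(H, W, C)`.
#' @param classes output classes (default 3: benign, malignant, normal).
#' @return a `melascan_arch`.
#' @export
designed_cnn_spec <- function(input_shape = c(224L, 224L, 3L), classes = 3L) {
  architecture_spec("designed", input_shape, list(
    layer_rescale(1 / 255),
    layer_conv2d(32, 3, stride = 4, padding = "same"),
    layer_activation("relu"),
    layer_maxpool(2),
    layer_conv2d(64, 5, stride = 2, padding = "valid"),
    layer_activation("relu"),
    layer_maxpool(2),
    layer_flatten(),
    layer_dense(38, activation = "relu"),
    layer_dropout(0.2),
    layer_dense(classes, activation = "softmax")
  ))
}

#' Reference CNN architectures with 3-class heads
#'
#' Canonical AlexNet (5 conv, 3 maxpool), LeNet-5 (3 conv, 2 subsampling, 2
#' fully connected: 7 weighted/subsampling layers) and VGG-16 (13 conv, 5
#' pool, 3 fully connected) with the final classifier replaced by a
#' `classes`-way softmax.
#'
#' @param classes output classes (default 3).
#' @return named list of `melascan_arch` objects: `alexnet`, `lenet5`,
#'   `vgg16`.
#' @export
reference_specs <- function(classes = 3L) {
  alexnet <- architecture_spec("alexnet", c(227L, 227L, 3L), list(
    layer_conv2d(96, 11, stride = 4, padding = "valid", activation = "relu"),
    layer_maxpool(3, stride = 2),
    layer_conv2d(256, 5, stride = 1, padding = "same", activation = "relu"),
    layer_maxpool(3, stride = 2),
    layer_conv2d(384, 3, stride = 1, padding = "same", activation = "relu"),
    layer_conv2d(384, 3, stride = 1, padding = "same", activation = "relu"),
    layer_conv2d(256, 3, stride = 1, padding = "same", activation = "relu"),
    layer_maxpool(3, stride = 2),
    layer_flatten(),
    layer_dense(4096, activation = "relu"),
    layer_dropout(0.5),
    layer_dense(4096, activation = "relu"),
    layer_dropout(0.5),
    layer_dense(classes, activation = "softmax")
  ))
  lenet5 <- architecture_spec("lenet5", c(32L, 32L, 3L), list(
    layer_conv2d(6, 5, stride = 1, padding = "valid", activation = "tanh"),
    layer_maxpool(2),
    layer_conv2d(16, 5, stride = 1, padding = "valid", activation = "tanh"),
    layer_maxpool(2),
    layer_conv2d(120, 5, stride = 1, padding = "valid", activation = "tanh"),
    layer_flatten(),
    layer_dense(84, activation = "tanh"),
    layer_dense(classes, activation = "softmax")
  ))
  vgg_block <- function(filters, n) {
    unlist(lapply(seq_len(n), function(i)
      list(layer_conv2d(filters, 3, stride = 1, padding = "same",
                        activation = "relu"))), recursive = FALSE)
  }
  vgg16 <- architecture_spec("vgg16", c(224L, 224L, 3L), c(
    vgg_block(64, 2), list(layer_maxpool(2)),
    vgg_block(128, 2), list(layer_maxpool(2)),
    vgg_block(256, 3), list(layer_maxpool(2)),
    vgg_block(512, 3), list(layer_maxpool(2)),
    vgg_block(512, 3), list(layer_maxpool(2)),
    list(layer_flatten(),
         layer_dense(4096, activation = "relu"),
         layer_dense(4096, activation = "relu"),
         layer_dense(classes, activation = "softmax"))
  ))
  list(alexnet = alexnet, lenet5 = lenet5, vgg16 = vgg16)
}

#' Count layers of a given kind in an architecture
#'
#' @param spec a `melascan_arch`.
#' @param kind layer kind, e.g. `"conv"`.
#' @return integer count.
#' @export
count_layers <- function(spec, kind) {
  sum(vapply(spec$layers, function(l) l$kind == kind, logical(1)))
}
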