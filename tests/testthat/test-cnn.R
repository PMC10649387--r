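test_that("the designed network reproduces its reference shapes and counts", {
  spec <- designed_cnn_spec()
  shapes <- infer_shapes(spec)
  expect_equal(shapes[[2]], c(56L, 56L, 32L))   # conv 3x3 s4 same
  expect_equal(shapes[[4]], c(28L, 28L, 32L))   # maxpool 2
  expect_equal(shapes[[5]], c(12L, 12L, 64L))   # conv 5x5 s2 valid
  expect_equal(shapes[[7]], c(6L, 6L, 64L))     # maxpool 2
  expect_equal(shapes[[8]], 2304L)              # flatten
  expect_equal(shapes[[9]], 38L)
  expect_equal(shapes[[11]], 3L)
  p <- count_params(spec)
  expect_equal(p$per_layer[p$per_layer > 0], c(896, 51264, 87590, 117))
  expect_equal(p$total, 139867)
})

test_that("shape inference follows the same/valid conventions", {
  spec <- architecture_spec("t", c(57L, 57L, 1L), list(
    layer_maxpool(2),                                    # valid floor((57-2)/2)+1 = 28
    layer_conv2d(4, 5, stride = 2, padding = "valid"),   # floor((28-5)/2)+1 = 12
    layer_activation("relu"),                            # preserves shape
    layer_conv2d(2, 3, stride = 4, padding = "same")     # ceil(12/4) = 3
  ))
  sh <- infer_shapes(spec)
  expect_equal(sh[[1]][1:2], c(28L, 28L))
  expect_equal(sh[[2]], c(12L, 12L, 4L))
  expect_equal(sh[[3]], c(12L, 12L, 4L))
  expect_equal(sh[[4]], c(3L, 3L, 2L))
  bad <- architecture_spec("b", c(4L, 4L, 1L), list(
    layer_conv2d(2, 5, stride = 1, padding = "valid"),
    layer_conv2d(2, 5, stride = 1, padding = "valid")
  ))
  expect_error(infer_shapes(bad), "nonpositive")
})

test_that("parameter counting uses the conv and dense closed forms", {
  spec <- architecture_spec("t", c(8L, 8L, 3L), list(
    layer_conv2d(32, 3, stride = 1, padding = "same"),  # 3*3*3*32 + 32 = 896
    layer_maxpool(2),
    layer_flatten(),
    layer_dense(38)                                     # 4*4*32*38 + 38
  ))
  p <- count_params(spec)
  expect_equal(p$per_layer[1], 896)
  expect_equal(p$per_layer[2], 0)
  expect_equal(p$per_layer[4], 4 * 4 * 32 * 38 + 38)
})

test_that("reference architectures match their canonical layer counts", {
  refs <- reference_specs()
  expect_equal(count_layers(refs$alexnet, "conv"), 5)
  expect_equal(count_layers(refs$alexnet, "maxpool"), 3)
  expect_equal(count_layers(refs$vgg16, "conv"), 13)
  expect_equal(count_layers(refs$vgg16, "maxpool"), 5)
  expect_equal(count_layers(refs$vgg16, "dense"), 3)
  expect_equal(count_layers(refs$lenet5, "conv") +
               count_layers(refs$lenet5, "maxpool") +
               count_layers(refs$lenet5, "dense"), 7)
  # every head is 3-class
  for (r in refs) expect_equal(utils::tail(infer_shapes(r), 1)[[1]], 3L)
})

tiny_spec <- function() {
  architecture_spec("tiny", c(12L, 12L, 1L), list(
    layer_rescale(1 / 255),
    layer_conv2d(4, 3, stride = 2, padding = "same"),
    layer_activation("relu"),
    layer_maxpool(2),
    layer_conv2d(3, 3, stride = 1, padding = "valid", activation = "relu"),
    layer_flatten(),
    layer_dense(6, activation = "relu"),
    layer_dropout(0.2),
    layer_dense(3, activation = "softmax")
  ))
}

tiny_data <- function(n_per_class = 8, seed = 50) {
  set.seed(seed)
  xs <- list(); ys <- integer(0)
  for (cl in 1:3) {
    for (i in seq_len(n_per_class)) {
      base <- matrix(c(40, 130, 220)[cl], 12, 12)
      xs[[length(xs) + 1]] <- array(pmin(pmax(base + rnorm(144, 0, 15), 0), 255),
                                    dim = c(12, 12, 1))
      ys <- c(ys, cl)
    }
  }
  list(x = xs, y = ys)
}

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("melascan")
  spec <- tiny_spec()
  model <- cnn_init(spec, seed = 42)
  set.seed(9)
  x <- array(runif(144, 0, 255), dim = c(12, 12, 1))
  loss_fn <- function(m) -log(ns$cnn_forward(m, x, train = FALSE)$probs[2])
  fwd <- ns$cnn_forward(model, x, train = FALSE)
  dlog <- fwd$probs; dlog[2] <- dlog[2] - 1
  bw <- ns$cnn_backward(model, fwd, dlog, train = FALSE)
  eps <- 1e-5
  for (li in seq_along(model$layers)) {
    if (is.null(bw$grads[[li]])) next
    set.seed(li)
    for (ii in sample(length(model$layers[[li]]$W), 6)) {
      m2 <- model
      m2$layers[[li]]$W[ii] <- model$layers[[li]]$W[ii] + eps
      lp <- loss_fn(m2)
      m2$layers[[li]]$W[ii] <- model$layers[[li]]$W[ii] - eps
      lm <- loss_fn(m2)
      expect_equal(bw$grads[[li]]$dW[ii], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training is seeded-deterministic and epochs = 0 is a no-op", {
  spec <- tiny_spec()
  d <- tiny_data()
  r1 <- cnn_train(spec, d$x, d$y, epochs = 1, batch_size = 8, seed = 7)
  r2 <- cnn_train(spec, d$x, d$y, epochs = 1, batch_size = 8, seed = 7)
  expect_identical(r1$history$loss, r2$history$loss)
  r0 <- cnn_train(spec, d$x, d$y, epochs = 0, seed = 7)
  expect_equal(nrow(r0$history), 0)
  init <- cnn_init(spec, seed = 7)
  expect_identical(r0$model$layers[[2]]$W, init$layers[[2]]$W)
})

test_that("softmax probabilities sum to one for arbitrary inputs", {
  spec <- tiny_spec()
  d <- tiny_data(n_per_class = 2, seed = 51)
  model <- cnn_init(spec, seed = 3)
  probs <- predict(model, d$x)
  expect_equal(dim(probs), c(6L, 3L))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-12)
  expect_true(all(probs >= 0))
})

test_that("a few epochs separate three intensity classes", {
  spec <- tiny_spec()
  d <- tiny_data(n_per_class = 10, seed = 52)
  res <- cnn_train(spec, d$x, d$y, epochs = 8, batch_size = 8, lr = 1e-2, seed = 1)
  expect_gt(utils::tail(res$history$accuracy, 1), 1 / 3)
})

test_that("grad-cam follows its defining formula", {
  # linear conv so the hand formula has no activation gating
  spec <- architecture_spec("g", c(4L, 4L, 1L), list(
    layer_conv2d(2, 3, stride = 1, padding = "same", activation = "linear"),
    layer_flatten(),
    layer_dense(2, activation = "softmax")
  ))
  model <- cnn_init(spec, seed = 1)
  set.seed(2)
  x <- matrix(runif(16, 0, 255), 4, 4)
  cam <- grad_cam(model, x, class = 1)
  expect_equal(dim(cam), c(4L, 4L))
  expect_true(all(cam >= 0 & cam <= 1))
  # hand evaluation: weights are spatial means of the dense rows feeding the logit
  ns <- asNamespace("melascan")
  fwd <- ns$cnn_forward(model, array(x, c(4, 4, 1)), train = FALSE)
  A <- fwd$outs[[1]]
  g <- array(model$layers[[3]]$W[, 1], c(4, 4, 2))
  wk <- apply(g, 3, mean)
  expected <- pmax(wk[1] * A[, , 1] + wk[2] * A[, , 2], 0)
  if (max(expected) > 0) expected <- expected / max(expected)
  expect_equal(cam, expected)
  # invariant to adding a constant to every class score
  shifted <- model
  shifted$layers[[3]]$b <- shifted$layers[[3]]$b + 5
  expect_equal(grad_cam(shifted, x, class = 1), cam)
  # zero gradient gives a zero heatmap
  dead <- model
  dead$layers[[3]]$W[, 1] <- 0
  expect_true(all(grad_cam(dead, x, class = 1) == 0))
  expect_error(grad_cam(model, x, class = 9), "out of range")
})
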