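test_that("intensity histogram counts every level and normalises", {
  img <- matrix(7, 4, 4)
  h <- intensity_histogram(img)
  expect_equal(h$counts[8], 16)
  expect_equal(h$p[8], 1)
  half <- matrix(c(rep(50, 8), rep(200, 8)), 4, 4)
  h2 <- intensity_histogram(half)
  expect_equal(h2$p[51], 0.5)
  expect_equal(h2$p[201], 0.5)
  img3 <- random_gray(13, 9, seed = 21)
  h3 <- intensity_histogram(img3)
  expect_equal(sum(h3$counts), 13 * 9)
  expect_equal(sum(h3$p), 1, tolerance = 1e-12)
})

test_that("maximum-entropy threshold matches the worked cases", {
  expect_error(max_entropy_threshold(matrix(42, 5, 5)), "constant")
  half <- matrix(c(rep(50, 8), rep(200, 8)), 4, 4)
  th <- max_entropy_threshold(half)
  expect_equal(th$threshold, 50)  # smallest maximising threshold
  expect_equal(th$entropy, 0)     # each class is one level
  # three-level image agrees with the exhaustive oracle
  img <- matrix(c(rep(30, 20), rep(120, 24), rep(220, 20)), 8, 8)
  th3 <- max_entropy_threshold(img)
  or <- kapur_oracle(img)
  expect_equal(th3$threshold, or$threshold)
  expect_equal(th3$entropy, or$entropy, tolerance = 1e-10)
})

test_that("maximum-entropy threshold equals the exhaustive oracle on random images", {
  for (s in 1:30) {
    img <- random_gray(16, 16, seed = 100 + s,
                       levels = sample(3:255, sample(3:30, 1)))
    th <- max_entropy_threshold(img)
    or <- kapur_oracle(img)
    expect_equal(th$threshold, or$threshold, label = paste("seed", s))
    expect_equal(th$entropy, or$entropy, tolerance = 1e-10)
  }
})

test_that("binarisation takes the darker side as lesion foreground", {
  half <- matrix(c(rep(50, 8), rep(200, 8)), 4, 4)
  m <- binarize(half, 50)
  expect_identical(m, half == 50)
  expect_false(any(binarize(matrix(200, 3, 3), 100)))  # all pixels above t
  # complement relation on the inverted image
  img <- random_gray(10, 10, seed = 22)
  t <- 130L
  expect_identical(binarize(img, t), !binarize(255 - img, 254 - t))
  expect_error(binarize(img, 300), "255")
})

test_that("corner cleanup removes exactly the corner-connected components", {
  m <- matrix(FALSE, 9, 9)
  m[1:3, 1:3] <- TRUE        # touches corner (1,1)
  m[5:6, 5:6] <- TRUE        # interior blob
  out <- corner_cleanup(m)
  expect_false(any(out[1:3, 1:3]))
  expect_true(all(out[5:6, 5:6]))
  expect_identical(corner_cleanup(matrix(FALSE, 4, 4)), matrix(FALSE, 4, 4))
  # edge contact without corner contact is retained
  m2 <- matrix(FALSE, 9, 9)
  m2[4:6, 1] <- TRUE
  expect_identical(corner_cleanup(m2), m2)
  # never adds foreground
  set.seed(23)
  for (i in 1:20) {
    r <- matrix(runif(64) < 0.4, 8, 8)
    expect_true(all(corner_cleanup(r) <= r))
  }
})

test_that("morphological refinement fills holes and drops specks", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[5, 5] <- FALSE
  out <- morph_refine(ring, min_area = 4, close_size = 3)
  expect_true(out[5, 5])
  speck <- matrix(FALSE, 10, 10); speck[5, 5] <- TRUE
  expect_false(any(morph_refine(speck, min_area = 20)))
  empty <- matrix(FALSE, 6, 6)
  expect_identical(morph_refine(empty), empty)
  # closing does not roughen the boundary of a jagged ellipse
  les <- make_lesion(lesion_params("malignant", seed = 9, size = 128, noise_sd = 0))
  boundary_px <- function(m) {
    interior <- m &
      rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
    sum(m & !interior)
  }
  refined <- morph_refine(les$mask)
  expect_lte(boundary_px(refined), boundary_px(les$mask))
  # refinement of a single large component never removes its pixels
  # (hole filling and closing are both extensive)
  expect_true(all(refined[les$mask]))
})

test_that("mask application zeroes the background only", {
  img <- random_gray(6, 6, seed = 24)
  full <- matrix(TRUE, 6, 6)
  expect_identical(apply_mask(img, full), img)
  none <- matrix(FALSE, 6, 6)
  expect_true(all(apply_mask(img, none) == 0))
  half <- matrix(rep(c(TRUE, FALSE), each = 18), 6, 6)
  out <- apply_mask(img, half)
  expect_identical(out[half], img[half])
  expect_true(all(out[!half] == 0))
  expect_error(apply_mask(img, matrix(TRUE, 3, 3)), "shape")
})

test_that("the full chain recovers synthetic ground truth", {
  ious <- vapply(1:10, function(s) {
    les <- make_lesion(lesion_params("benign", seed = 40 + s))
    seg <- segment_lesion(les$image)
    mask_iou(seg$mask, les$mask)
  }, numeric(1))
  expect_gte(median(ious), 0.8)
})
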