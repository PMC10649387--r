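test_that("first-order statistics use population variance over the mask", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  fo <- first_order(img, matrix(TRUE, 2, 2))
  expect_equal(fo$min_gray, 1)
  expect_equal(fo$max_gray, 4)
  expect_equal(fo$mean, 2.5)
  expect_equal(fo$sd, sqrt(1.25))
  expect_equal(fo$cov, sqrt(1.25) / 2.5)
  const <- matrix(77, 4, 4)
  fc <- first_order(const, matrix(TRUE, 4, 4))
  expect_equal(fc$sd, 0)
  expect_equal(fc$cov, 0)
  expect_equal(fc$hist_width, 0)
  expect_equal(c(fc$min_gray, fc$max_gray, fc$median), c(77, 77, 77))
  # single-pixel mask
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  f1 <- first_order(img = matrix(9, 3, 3), mask = one)
  expect_equal(f1$mean, 9)
  expect_equal(f1$sd, 0)
  expect_error(first_order(const, matrix(FALSE, 4, 4)), "foreground")
  # zero mean yields the NaN sentinel for the coefficient of variation
  f0 <- first_order(matrix(0, 2, 2), matrix(TRUE, 2, 2))
  expect_true(is.nan(f0$cov))
})

test_that("GLCM builder matches the pair-enumeration oracle on the worked image", {
  img <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 2, 2, 2), c(2, 2, 3, 3)) + 1
  mask <- matrix(TRUE, 4, 4)
  g <- glcm_compute(img, mask, levels = 4, offsets = list(c(0L, 1L)), rebin = FALSE)
  expect_equal(g$counts, glcm_oracle(img, mask, 4, list(c(0L, 1L))))
  expect_equal(g$counts[1, 1], 4)
  expect_identical(g$counts, t(g$counts))
  expect_equal(sum(g$probs), 1)
  # constant image: single cell carries all mass
  gc <- glcm_compute(matrix(100, 5, 5), levels = 8)
  expect_equal(sum(gc$probs > 0), 1)
  expect_equal(max(gc$probs), 1)
})

test_that("GLCM features follow their closed forms", {
  gc <- glcm_compute(matrix(100, 5, 5), levels = 8)
  f <- glcm_features(gc)
  expect_equal(f$idm, 1)
  expect_equal(f$diff_entropy, 0)
  # single occupied level l contributes sum-average 2l
  l <- as.integer(100 * 8 / 256) + 1
  expect_equal(f$sum_average, 2 * l)
  # worked image: direct summation oracle over the brute-force matrix
  img <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 2, 2, 2), c(2, 2, 3, 3)) + 1
  g <- glcm_compute(img, levels = 4, offsets = list(c(0L, 1L)), rebin = FALSE)
  p <- g$probs
  idm <- 0; sv <- 0; de_acc <- rep(0, 4)
  for (i in 1:4) for (j in 1:4) {
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    sv <- sv + (i + j) * p[i, j]
    de_acc[abs(i - j) + 1] <- de_acc[abs(i - j) + 1] + p[i, j]
  }
  de <- -sum(de_acc[de_acc > 0] * log2(de_acc[de_acc > 0]))
  f2 <- glcm_features(g)
  expect_equal(f2$idm, idm)
  expect_equal(f2$sum_average, sv)
  expect_equal(f2$diff_entropy, de)
  expect_true(f2$idm > 0 && f2$idm <= 1)
  expect_gte(f2$diff_entropy, 0)
})

test_that("GLSZM zones, conservation, and features match hand arithmetic", {
  img <- rbind(c(1, 1, 2), c(1, 2, 2), c(3, 3, 3))
  z <- glszm_compute(img, levels = 4, rebin = FALSE)
  expect_equal(z$nz, 3)
  expect_equal(sum(z$counts[, 3]), 3)  # three zones of size 3
  expect_equal(sum(col(z$counts) * z$counts), 9)
  f <- glszm_features(z)
  expect_equal(f$glv, 2 / 3, tolerance = 1e-9)
  expect_equal(f$zse, log2(3), tolerance = 1e-6)
  # constant mask: one zone covering all pixels
  zc <- glszm_compute(matrix(50, 4, 4), levels = 8)
  expect_equal(zc$nz, 1)
  fc <- glszm_features(zc)
  expect_equal(fc$glv, 0)
  expect_equal(fc$zse, 0, tolerance = 1e-6)
  # entropy bound
  expect_lte(f$zse, log2(sum(z$counts > 0)) + 1e-9)
  expect_error(glszm_compute(img, mask = matrix(FALSE, 3, 3), levels = 4), "foreground")
})

test_that("texture builders agree with brute-force oracles on random instances", {
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  set.seed(300)
  for (i in 1:60) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    levels <- sample(2:4, 1)
    lev <- matrix(sample(seq_len(levels), nr * nc, TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (!any(mask)) mask[1, 1] <- TRUE
    zo <- glszm_oracle(lev, mask, levels)
    zz <- glszm_compute(lev, mask, levels = levels, rebin = FALSE)
    expect_equal(zz$counts, zo, ignore_attr = TRUE, label = paste("glszm", i))
    expect_equal(sum(col(zz$counts) * zz$counts), sum(mask))
    go <- glcm_oracle(lev, mask, levels, offsets)
    if (sum(go) > 0) {
      gg <- glcm_compute(lev, mask, levels = levels, offsets = offsets, rebin = FALSE)
      expect_equal(gg$counts, go, ignore_attr = TRUE, label = paste("glcm", i))
    }
  }
})

test_that("GLSZM features are rotation invariant", {
  set.seed(301)
  for (i in 1:10) {
    img <- random_gray(12, 9, seed = 400 + i)
    mask <- matrix(runif(12 * 9) < 0.7, 12, 9)
    if (sum(mask) < 2) next
    rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
    f1 <- glszm_features(glszm_compute(img, mask, levels = 8))
    img_r <- rot90(img)
    mask_r <- rot90(mask)
    f2 <- glszm_features(glszm_compute(img_r, mask_r, levels = 8))
    expect_equal(f1$glv, f2$glv)
    expect_equal(f1$zse, f2$zse)
  }
})

test_that("geometry reports component area and near-analytic perimeter", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(geometric_features(one)$area, 1)
  rect <- matrix(FALSE, 20, 20); rect[4:12, 5:10] <- TRUE
  expect_equal(geometric_features(rect)$area, 9 * 6)
  disk <- disk_mask(64, 20)
  geo <- geometric_features(disk)
  expect_equal(geo$area, sum(disk))
  expect_lt(abs(geo$perimeter - 2 * pi * 20) / (2 * pi * 20), 0.05)
  # largest component wins
  two <- disk_mask(64, 10)
  two[2:3, 2:3] <- TRUE
  expect_equal(geometric_features(two)$area, sum(disk_mask(64, 10)))
  expect_error(geometric_features(matrix(FALSE, 4, 4)), "foreground")
})

test_that("the full feature vector is finite, deterministic, and schema-complete", {
  les <- make_lesion(lesion_params("benign", seed = 17, size = 128))
  fv <- extract_features(les$image, les$mask)
  expect_identical(names(fv), feature_schema()$name)
  expect_true(all(is.finite(unlist(fv))))
  expect_true(fv$min_gray <= fv$median && fv$median <= fv$max_gray)
  expect_gte(fv$area, 0)
  fv2 <- extract_features(les$image, les$mask)
  expect_identical(fv, fv2)
})

test_that("malignant lesions are larger than benign on average", {
  n <- 25
  areas <- function(cl, base) vapply(seq_len(n), function(s) {
    sum(make_lesion(lesion_params(cl, seed = base + s))$mask)
  }, numeric(1))
  expect_gt(mean(areas("malignant", 600)), mean(areas("benign", 700)))
})

test_that("group summary reports per-class moments and quartiles", {
  tab <- data.frame(x = c(1, 2, 3, 10, 20, 30),
                    label = rep(c("a", "b"), each = 3))
  gs <- group_summary(tab)
  a <- gs[gs$label == "a" & gs$feature == "x", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)       # sample standard deviation
  expect_equal(a$median, 2)
  single <- data.frame(x = c(5, 6), label = c("a", "a"))
  gs2 <- group_summary(single)
  expect_equal(nrow(gs2), 1)
  lone <- data.frame(x = 5, label = "a")
  expect_true(is.na(group_summary(lone)$sd))
})
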