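# Denoising filter bank. Every filter maps a grayscale [0, 255] matrix to a
# same-shaped matrix in range, and leaves constant images untouched.

shift_mat <- function(m, dr, dc) {
  # replicate-padded shift: value at (r, c) becomes m[clamp(r+dr), clamp(c+dc)]
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

denoise_median <- function(img, size = 3L) {
  radius <- (as.integer(size) - 1L) %/% 2L
  unebi(EBImage::medianFilter(ebi(img), size = radius))
}

denoise_gaussian <- function(img, sigma = 1) {
  unebi(EBImage::gblur(ebi(img), sigma = sigma, boundary = "replicate"))
}

denoise_bilateral <- function(img, sigma_spatial = 2, sigma_range = 25, radius = 3L) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    ws <- exp(-(dr^2 + dc^2) / (2 * sigma_spatial^2))
    nb <- shift_mat(img, dr, dc)
    w <- ws * exp(-(nb - img)^2 / (2 * sigma_range^2))
    num <- num + w * nb
    den <- den + w
  }
  clip255(num / den)
}

denoise_nlm <- function(img, h = 10, patch = 3L, search = 7L) {
  prad <- (patch - 1L) %/% 2L
  srad <- (search - 1L) %/% 2L
  box <- matrix(1 / patch^2, patch, patch)
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  for (dr in -srad:srad) {
    for (dc in -srad:srad) {
      nb <- shift_mat(img, dr, dc)
      d2 <- local_filter((img - nb)^2, box)  # mean squared patch difference
      w <- exp(-pmax(d2, 0) / h^2)
      num <- num + w * nb
      den <- den + w
    }
  }
  clip255(num / den)
}

# DCT-II orthonormal transform matrix of order n.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  d <- sqrt(2 / n) * cos(outer(k, k + 0.5) * pi / n)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

# Single-stage hard-threshold block-matching 3D filter: groups of similar
# 8 x 8 blocks are stacked, transformed with separable DCTs in all three
# dimensions, hard-thresholded at lambda * sigma, inverted and aggregated
# with weights inversely proportional to the number of retained
# coefficients.
denoise_bm3d <- function(img, sigma = 10, block = 8L, stride = 4L,
                         search_steps = 3L, max_group = 16L, lambda = 2.7) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < block || nc < block) return(denoise_gaussian(img, sigma = 1))
  rs <- unique(c(seq(1L, nr - block + 1L, by = stride), nr - block + 1L))
  cs <- unique(c(seq(1L, nc - block + 1L, by = stride), nc - block + 1L))
  grid <- expand.grid(r = rs, c = cs)
  nb <- nrow(grid)
  # all blocks as columns of a (block^2 x nb) matrix
  blocks <- matrix(0, block * block, nb)
  for (i in seq_len(nb))
    blocks[, i] <- img[grid$r[i]:(grid$r[i] + block - 1L),
                       grid$c[i]:(grid$c[i] + block - 1L)]
  gi <- match(grid$r, rs); gj <- match(grid$c, cs)
  index <- matrix(0L, length(rs), length(cs))
  index[cbind(gi, gj)] <- seq_len(nb)
  D <- dct_matrix(block)
  acc <- matrix(0, nr, nc); wacc <- matrix(0, nr, nc)
  thr <- lambda * sigma
  for (i in seq_len(nb)) {
    nei_i <- max(1L, gi[i] - search_steps):min(length(rs), gi[i] + search_steps)
    nei_j <- max(1L, gj[i] - search_steps):min(length(cs), gj[i] + search_steps)
    cand <- as.vector(index[nei_i, nei_j])
    d2 <- colMeans((blocks[, cand, drop = FALSE] - blocks[, i])^2)
    keep <- cand[order(d2)][seq_len(min(max_group, length(cand)))]
    g <- length(keep)
    # 2D DCT of each block in the group, then DCT along the stack
    grp <- array(blocks[, keep], dim = c(block, block, g))
    for (m in seq_len(g)) grp[, , m] <- D %*% grp[, , m] %*% t(D)
    if (g > 1) {
      Dg <- dct_matrix(g)
      gm <- matrix(grp, block * block, g) %*% t(Dg)
    } else {
      gm <- matrix(grp, block * block, g)
    }
    kept <- abs(gm) >= thr
    kept[1, 1] <- TRUE  # always keep the DC coefficient
    gm[!kept] <- 0
    if (g > 1) gm <- gm %*% Dg
    grp <- array(gm, dim = c(block, block, g))
    w <- 1 / max(sum(kept), 1)
    for (m in seq_len(g)) {
      bk <- t(D) %*% grp[, , m] %*% D
      r0 <- grid$r[keep[m]]; c0 <- grid$c[keep[m]]
      rows <- r0:(r0 + block - 1L); cols <- c0:(c0 + block - 1L)
      acc[rows, cols] <- acc[rows, cols] + w * bk
      wacc[rows, cols] <- wacc[rows, cols] + w
    }
  }
  out <- ifelse(wacc > 0, acc / pmax(wacc, .Machine$double.eps), img)
  clip255(out)
}

#' Denoise a grayscale image
#'
#' Filter bank used to clean dermoscopy images before segmentation: median
#' (3 x 3), Gaussian (sigma 1), bilateral, non-local means, and a
#' single-stage hard-threshold block-matching 3D (BM3D-style) filter.
#'
#' @param img grayscale matrix, intensities in [0, 255].
#' @param method one of `"median"`, `"gaussian"`, `"bilateral"`, `"nlm"`,
#'   `"bm3d"`.
#' @param ... filter parameters: `size` (median), `sigma` (gaussian, and the
#'   noise level for bm3d), `sigma_spatial`/`sigma_range` (bilateral),
#'   `h`/`patch`/`search` (nlm), `block`/`stride`/`max_group`/`lambda`
#'   (bm3d).
#' @return denoised matrix, same shape, intensities in [0, 255].
#' @export
denoise <- function(img, method = c("median", "gaussian", "bilateral", "nlm", "bm3d"),
                    ...) {
  img <- assert_gray(img)
  method <- match.arg(method)
  switch(method,
    median    = denoise_median(img, ...),
    gaussian  = denoise_gaussian(img, ...),
    bilateral = denoise_bilateral(img, ...),
    nlm       = denoise_nlm(img, ...),
    bm3d      = denoise_bm3d(img, ...)
  )
}

#' Remove hair strokes from a grayscale dermoscopy image
#'
#' DullRazor-style pipeline: dark curvilinear structures are detected with a
#' morphological black-hat (closing minus image) under linear structuring
#' elements at four orientations, thresholded, dilated by one pixel, and the
#' flagged pixels are restored by diffusion inpainting from their
#' surroundings. Hair-free images pass through essentially unchanged.
#'
#' @param img grayscale matrix, intensities in [0, 255].
#' @param length structuring-element length in pixels.
#' @param threshold black-hat response (intensity levels) above which a pixel
#'   is treated as hair.
#' @return list with `image` (inpainted matrix) and `mask` (logical hair mask).
#' @export
remove_hair <- function(img, length = 9L, threshold = 10) {
  img <- assert_gray(img)
  kerns <- list(
    matrix(1, 1, length),                # horizontal
    matrix(1, length, 1),                # vertical
    diag(length),                        # diagonal
    diag(length)[length:1, ]             # anti-diagonal
  )
  # black-hat on a median-smoothed copy: 3x3 medians suppress pixel noise but
  # keep strokes >= 2 px wide intact
  smoothed <- denoise_median(img, 3L)
  bh <- matrix(0, nrow(smoothed), ncol(smoothed))
  e <- ebi(smoothed)
  for (k in kerns) {
    closed <- EBImage::closing(e, k)
    bh <- pmax(bh, unebi(closed) - smoothed)
  }
  mask <- bh > threshold
  if (any(mask)) {
    # hair is at most a few pixels wide: discard flagged components that
    # survive a 3x3 erosion (too thick to be a stroke)
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1), matrix(1, 3, 3))) > 0.5
    lab <- label8(mask)
    thick <- unique(lab[er])
    thick <- thick[thick > 0L]
    if (length(thick)) mask[lab %in% thick] <- FALSE
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), matrix(1, 3, 3))) > 0.5
  }
  out <- inpaint_diffusion(img, mask)
  list(image = out, mask = mask)
}

# Replace masked pixels by iterative neighbourhood averaging (Jacobi
# diffusion) seeded from the unmasked pixels.
inpaint_diffusion <- function(img, mask, iters = 300L, tol = 1e-3) {
  if (!any(mask)) return(img)
  x <- img
  x[mask] <- mean(img[!mask])
  box <- matrix(1 / 9, 3, 3)
  for (i in seq_len(iters)) {
    sm <- local_filter(x, box)
    delta <- max(abs(sm[mask] - x[mask]))
    x[mask] <- sm[mask]
    if (delta < tol) break
  }
  clip255(x)
}
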