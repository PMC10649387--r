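# Image-quality metrics used to score the denoising filter bank against a
# reference image. All operate on grayscale matrices scaled [0, 255].

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Windowed local means via EBImage filter2 with replicated borders.
local_filter <- function(m, kern) {
  EBImage::imageData(EBImage::filter2(EBImage::Image(m), kern, boundary = "replicate"))
}

# Exact win x win sliding-window means ("valid" positions) via an integral
# image; works for any window size including even ones.
window_means <- function(m, win) {
  s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  s[-1L, -1L] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  nr <- nrow(m) - win + 1L; nc <- ncol(m) - win + 1L
  (s[(1L + win):(nrow(m) + 1L), (1L + win):(ncol(m) + 1L), drop = FALSE] -
     s[1L:nr, (1L + win):(ncol(m) + 1L), drop = FALSE] -
     s[(1L + win):(nrow(m) + 1L), 1L:nc, drop = FALSE] +
     s[1L:nr, 1L:nc, drop = FALSE]) / (win * win)
}

#' Mean squared error between two images
#'
#' @param a,b grayscale matrices of identical shape, intensities in [0, 255].
#' @return nonnegative scalar (squared intensity units).
#' @export
mse <- function(a, b) {
  a <- assert_gray(a, "a"); b <- assert_gray(b, "b")
  if (!identical(dim(a), dim(b))) stop("images must have identical shapes", call. = FALSE)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' PSNR = 10 log10(MAX^2 / MSE) with MAX = 255; `Inf` for identical images.
#'
#' @inheritParams mse
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b) {
  e <- mse(a, b)
  if (e == 0) return(Inf)
  10 * log10(255^2 / e)
}

#' Structural similarity index (SSIM)
#'
#' Mean-pooled SSIM map with the standard constants C1 = (0.01 * 255)^2,
#' C2 = (0.03 * 255)^2 and an 11 x 11 Gaussian window (sigma 1.5); the window
#' shrinks to the largest odd size that fits small images. Identical images
#' score exactly 1.
#'
#' @inheritParams mse
#' @return scalar in [-1, 1].
#' @export
ssim <- function(a, b) {
  a <- assert_gray(a, "a"); b <- assert_gray(b, "b")
  if (!identical(dim(a), dim(b))) stop("images must have identical shapes", call. = FALSE)
  win <- min(11L, if (min(dim(a)) %% 2L == 1L) min(dim(a)) else min(dim(a)) - 1L)
  win <- max(win, 1L)
  k <- gaussian_kernel(win, 1.5)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mu_a <- local_filter(a, k); mu_b <- local_filter(b, k)
  va <- local_filter(a * a, k) - mu_a^2
  vb <- local_filter(b * b, k) - mu_b^2
  vab <- local_filter(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * vab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Universal quality index (UQI)
#'
#' Wang-Bovik Q index: the SSIM form with no stabilising constants, averaged
#' over 8 x 8 sliding windows. Windows with zero denominator (locally
#' constant content) carry no structure and are excluded from the average;
#' if every window is degenerate (two constant images) the index is defined
#' as 0.
#'
#' @inheritParams mse
#' @return scalar in [-1, 1].
#' @export
uqi <- function(a, b) {
  a <- assert_gray(a, "a"); b <- assert_gray(b, "b")
  if (!identical(dim(a), dim(b))) stop("images must have identical shapes", call. = FALSE)
  win <- min(8L, dim(a))
  mu_a <- window_means(a, win); mu_b <- window_means(b, win)
  va <- window_means(a * a, win) - mu_a^2
  vb <- window_means(b * b, win) - mu_b^2
  vab <- window_means(a * b, win) - mu_a * mu_b
  num <- 4 * vab * mu_a * mu_b
  den <- (va + vb) * (mu_a^2 + mu_b^2)
  ok <- abs(den) > 1e-10
  if (!any(ok)) return(0)
  mean(num[ok] / den[ok])
}

#' All four image-quality metrics at once
#'
#' @inheritParams mse
#' @return list with elements `mse`, `psnr_db`, `ssim`, `uqi`.
#' @export
quality_metrics <- function(a, b) {
  list(mse = mse(a, b), psnr_db = psnr(a, b), ssim = ssim(a, b), uqi = uqi(a, b))
}
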