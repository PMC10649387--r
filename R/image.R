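#' @useDynLib melascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Raster images are plain numeric matrices (grayscale) or H x W x 3 arrays
# (RGB), intensities on the 8-bit scale [0, 255], row 1 = top of the image,
# indexed (row, col). All exported image operations accept and return this
# representation.

assert_raster <- function(img, what = "img") {
  if (is.matrix(img)) {
    ok <- TRUE
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] %in% c(1L, 3L)) {
    ok <- TRUE
  } else {
    ok <- FALSE
  }
  if (!ok) stop(what, " must be a numeric matrix or an H x W x {1,3} array", call. = FALSE)
  if (anyNA(img)) stop(what, " contains missing values", call. = FALSE)
  rng <- range(img)
  if (rng[1] < -1e-8 || rng[2] > 255 + 1e-8)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

assert_gray <- function(img, what = "img") {
  assert_raster(img, what)
  if (!is.matrix(img)) {
    if (dim(img)[3] == 1L) return(invisible(img[, , 1L, drop = TRUE]))
    stop(what, " must be a single-channel (grayscale) image", call. = FALSE)
  }
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# EBImage interop: EBImage stores images with the matrix's first dimension on
# its x axis. All kernels built here live in (row, col) space, and resize
# targets are passed so that the returned matrix has the requested (rows,
# cols); no transposition is needed except at file I/O boundaries.
ebi <- function(m) EBImage::Image(m / 255)
unebi <- function(e) clip255(EBImage::imageData(e) * 255)

#' Read an 8-bit PNG or JPEG image
#'
#' Returns a grayscale matrix or an H x W x 3 array on the [0, 255] scale.
#' Alpha channels are dropped.
#'
#' @param path file path; format chosen from the extension.
#' @return numeric matrix (grayscale) or H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    x <- EBImage::imageData(EBImage::readImage(path))
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L, drop = TRUE]
  if (length(dim(x)) == 3L && dim(x)[3] == 2L) x <- x[, , 1L, drop = TRUE]  # gray+alpha
  round(clip255(x * 255))
}

#' Write an image to PNG or JPEG
#'
#' @param img grayscale matrix or H x W x 3 array, intensities in [0, 255].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_raster(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    x <- img / 255
    x <- if (is.matrix(x)) t(x) else aperm(x, c(2L, 1L, 3L))
    EBImage::writeImage(EBImage::Image(x,
      colormode = if (is.matrix(img)) "Grayscale" else "Color"), path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Luma conversion with ITU-R BT.601 weights (0.299, 0.587, 0.114), rounded
#' to the nearest integer level. Grayscale input passes through unchanged.
#'
#' @param img H x W x 3 array or grayscale matrix, intensities in [0, 255].
#' @return grayscale matrix of the same height and width.
#' @export
to_grayscale <- function(img) {
  assert_raster(img)
  if (is.matrix(img)) return(img)
  if (dim(img)[3] == 1L) return(img[, , 1L, drop = TRUE])
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  matrix(clip255(round(g)), dim(img)[1], dim(img)[2])
}

#' Resize an image
#'
#' Bilinear interpolation; downscaling first smooths with a Gaussian matched
#' to the scale factor to avoid aliasing.
#'
#' @param img grayscale matrix or H x W x 3 array.
#' @param h,w target numbers of rows and columns (positive integers).
#' @return resized image with dimensions exactly (h, w).
#' @export
resize_image <- function(img, h, w) {
  assert_raster(img)
  if (length(h) != 1L || length(w) != 1L || h < 1 || w < 1)
    stop("target dimensions must be positive", call. = FALSE)
  h <- as.integer(h); w <- as.integer(w)
  resize1 <- function(m) {
    if (nrow(m) == h && ncol(m) == w) return(m)
    sy <- nrow(m) / h; sx <- ncol(m) / w
    if (max(sy, sx) > 1) {
      sigma <- 0.5 * sqrt(max(max(sy, sx)^2 - 1, 0))
      # gblur's kernel must fit inside the image
      sigma <- min(sigma, (min(dim(m)) - 3) / 8)
      if (sigma > 0.1) m <- unebi(EBImage::gblur(ebi(m), sigma = sigma, boundary = "replicate"))
    }
    clip255(unebi(EBImage::resize(ebi(m), w = h, h = w, filter = "bilinear")))
  }
  if (is.matrix(img)) return(resize1(img))
  out <- array(0, dim = c(h, w, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- resize1(img[, , k])
  out
}
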