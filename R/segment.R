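# Maximum-entropy lesion segmentation: histogram -> Kapur threshold ->
# dark-side binarisation -> corner cleanup -> morphological refinement.

#' Intensity histogram of a grayscale image
#'
#' @param img grayscale matrix, intensities in [0, 255].
#' @return list with `counts` (256 integer bins for levels 0..255) and `p`
#'   (probabilities summing to 1).
#' @export
intensity_histogram <- function(img) {
  img <- assert_gray(img)
  counts <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  list(counts = counts, p = counts / sum(counts))
}

#' Maximum-entropy (Kapur) threshold
#'
#' Scans all 256 candidate thresholds t and returns the one maximising the
#' Kapur criterion H_bg(t) + H_fg(t), the sum of the Shannon entropies (base
#' 2) of the renormalised class histograms for levels <= t and > t. Only
#' candidates with both classes nonempty are admissible; ties are broken by
#' the smallest t. 0 * log2(0) is taken as 0.
#'
#' @param img grayscale matrix with at least two distinct levels.
#' @return list with `threshold` (gray level, 0..255) and `entropy` (the
#'   criterion value at the optimum, bits).
#' @export
max_entropy_threshold <- function(img) {
  h <- intensity_histogram(img)
  p <- h$p
  if (sum(p > 0) < 2L) stop("image is constant: no threshold exists", call. = FALSE)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  cp <- cumsum(p)          # P(level <= t), index t+1
  cs <- cumsum(plogp)      # sum p log2 p over levels <= t
  tot <- cs[256L]
  crit <- rep(-Inf, 256L)
  for (t in 0:254) {
    p1 <- cp[t + 1L]
    if (p1 <= 0 || p1 >= 1) next
    h_bg <- log2(p1) - cs[t + 1L] / p1
    h_fg <- log2(1 - p1) - (tot - cs[t + 1L]) / (1 - p1)
    crit[t + 1L] <- h_bg + h_fg
  }
  best <- which.max(crit)  # first maximum = smallest t
  list(threshold = best - 1L, entropy = crit[best])
}

#' Binarise an image at a threshold, dark side as foreground
#'
#' Dermoscopic lesions are darker than the surrounding skin, so the
#' foreground is the class of pixels with intensity <= t (the class whose
#' mean intensity is necessarily the lower of the two).
#'
#' @param img grayscale matrix.
#' @param t threshold gray level in [0, 255].
#' @return logical matrix, `TRUE` = lesion foreground.
#' @export
binarize <- function(img, t) {
  img <- assert_gray(img)
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]", call. = FALSE)
  img <= t
}

label8 <- function(mask) {
  .label_components(matrix(ifelse(mask, 1L, NA_integer_), nrow(mask)), 8L)
}

#' Remove foreground components touching an image corner
#'
#' Bright corner regions in a dark-side mask are dermoscopy vignetting, not
#' lesion: every 8-connected foreground component containing one of the four
#' corner pixels is deleted.
#'
#' @param mask logical matrix.
#' @return logical matrix, never with more foreground than the input.
#' @export
corner_cleanup <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label8(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  corner_labs <- unique(lab[cbind(c(1L, 1L, nr, nr), c(1L, nc, 1L, nc))])
  corner_labs <- corner_labs[corner_labs > 0L]
  if (length(corner_labs)) mask[lab %in% corner_labs] <- FALSE
  mask
}

#' Morphological refinement of a lesion mask
#'
#' Removes 8-connected components below `min_area` pixels, fills interior
#' holes, then applies a morphological closing with a disc to smooth the
#' jagged boundary that thresholding leaves.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels (default 64, sized for
#'   256 x 256 images).
#' @param close_size diameter of the closing disc (default 5).
#' @return refined logical matrix; an empty mask passes through.
#' @export
morph_refine <- function(mask, min_area = 64L, close_size = 5L) {
  if (!any(mask)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  mask <- matrix(lab %in% keep, nrow(mask))
  if (!any(mask)) return(mask)
  e <- EBImage::Image(mask * 1)
  e <- EBImage::fillHull(e)
  brush <- EBImage::makeBrush(close_size, shape = "disc")
  e <- EBImage::closing(e, brush)
  e <- EBImage::fillHull(e)
  EBImage::imageData(e) > 0.5
}

#' Apply a binary mask to an image
#'
#' @param img grayscale matrix.
#' @param mask logical matrix of the same shape.
#' @return matrix with background pixels set to 0, foreground unchanged.
#' @export
apply_mask <- function(img, mask) {
  img <- assert_gray(img)
  if (!identical(dim(img), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  img * mask
}

#' Full lesion segmentation chain
#'
#' Kapur threshold, dark-side binarisation, corner cleanup, and
#' morphological refinement in one call.
#'
#' @param img grayscale matrix, intensities in [0, 255].
#' @param min_area,close_size passed to [morph_refine()].
#' @return list with `mask` (logical), `threshold`, `entropy`, and
#'   `segmented` (the masked image).
#' @export
segment_lesion <- function(img, min_area = 64L, close_size = 5L) {
  th <- max_entropy_threshold(img)
  mask <- binarize(img, th$threshold)
  mask <- corner_cleanup(mask)
  mask <- morph_refine(mask, min_area = min_area, close_size = close_size)
  list(mask = mask, threshold = th$threshold, entropy = th$entropy,
       segmented = apply_mask(img, mask))
}

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of identical shape.
#' @return scalar in [0, 1]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
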