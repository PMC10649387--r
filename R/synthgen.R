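# Seeded generators for dermoscopy-like lesion images (with ground-truth
# masks) and feature tables, so every stage of the pipeline is testable
# without external image downloads. Class geometry targets (area, lesion
# darkness) follow the benign/malignant feature statistics used throughout
# the package; see feature_schema().

#' Parameters of one synthetic lesion image
#'
#' Defaults emulate a dermoscopic field: a bright, slightly textured skin
#' background with an embedded darker elliptical lesion whose boundary is
#' sinusoidally perturbed. Benign lesions are smaller and rounder (expected
#' area 6727 px at 256 x 256), malignant larger and more irregular (expected
#' area 13,010 px); `"normal"` produces background only. Gaussian pixel
#' noise and optional dark hair strokes can be added.
#'
#' @param class `"benign"`, `"malignant"`, or `"normal"`.
#' @param seed integer seed; every stochastic element derives from it.
#' @param size image side in pixels.
#' @param bg_mean,bg_sd background intensity mean and low-frequency
#'   variation.
#' @param lesion_mean mean lesion intensity (darker than the background);
#'   class default 68 (benign) / 76 (malignant).
#' @param area_mean,area_sd lesion area target (px); class defaults from the
#'   benign/malignant area statistics.
#' @param irregularity relative amplitude of the sinusoidal boundary
#'   perturbation; class default 0.03 (benign) / 0.12 (malignant).
#' @param noise_sd additive Gaussian noise sigma.
#' @param n_hair number of dark hair strokes.
#' @return a `lesion_params` list.
#' @export
lesion_params <- function(class = c("benign", "malignant", "normal"), seed = 0L,
                          size = 256L, bg_mean = 180, bg_sd = 8,
                          lesion_mean = NULL, area_mean = NULL, area_sd = NULL,
                          irregularity = NULL, noise_sd = 4, n_hair = 0L) {
  class <- match.arg(class)
  sc <- feature_schema()
  areas <- sc[sc$name == "area", ]
  defaults <- switch(class,
    benign = list(lesion_mean = 68, area_mean = areas$benign_mean,
                  area_sd = areas$benign_sd, irregularity = 0.03,
                  aspect = c(0.85, 1.0)),
    malignant = list(lesion_mean = 76, area_mean = areas$malignant_mean,
                     area_sd = areas$malignant_sd, irregularity = 0.12,
                     aspect = c(0.55, 0.9)),
    normal = list(lesion_mean = NA_real_, area_mean = 0, area_sd = 0,
                  irregularity = 0, aspect = c(1, 1))
  )
  structure(list(
    class = class, seed = as.integer(seed), size = as.integer(size),
    bg_mean = bg_mean, bg_sd = bg_sd,
    lesion_mean = if (is.null(lesion_mean)) defaults$lesion_mean else lesion_mean,
    area_mean = if (is.null(area_mean)) defaults$area_mean else area_mean,
    area_sd = if (is.null(area_sd)) defaults$area_sd else area_sd,
    irregularity = if (is.null(irregularity)) defaults$irregularity else irregularity,
    aspect = defaults$aspect, noise_sd = noise_sd, n_hair = as.integer(n_hair)
  ), class = "lesion_params")
}

smooth_noise <- function(size, sigma_blur, rng_sd = 1) {
  sigma_blur <- min(sigma_blur, (size - 3) / 8)  # gblur kernel must fit
  z <- matrix(stats::rnorm(size * size), size, size)
  z <- EBImage::imageData(EBImage::gblur(EBImage::Image(z), sigma = sigma_blur,
                                         boundary = "replicate"))
  z / stats::sd(z) * rng_sd
}

#' Generate one synthetic lesion image with its ground-truth mask
#'
#' @param params a [lesion_params()] list.
#' @return list with `image` (grayscale matrix, [0, 255]), `mask` (logical
#'   ground truth; all-FALSE for the `"normal"` class), and `label`.
#' @export
make_lesion <- function(params = lesion_params()) {
  stopifnot(inherits(params, "lesion_params"))
  set.seed(params$seed)
  n <- params$size
  img <- params$bg_mean + smooth_noise(n, sigma_blur = 24, rng_sd = params$bg_sd)
  mask <- matrix(FALSE, n, n)
  if (params$class != "normal") {
    area <- stats::rnorm(1, params$area_mean, params$area_sd)
    area <- min(max(area, 0.02 * n * n), 0.35 * n * n)
    q <- stats::runif(1, params$aspect[1], params$aspect[2])
    a <- sqrt(area / (pi * q)); b <- sqrt(area * q / pi)
    lim <- 0.42 * n
    if (max(a, b) * (1 + params$irregularity) > lim) {
      sc <- lim / (max(a, b) * (1 + params$irregularity)); a <- a * sc; b <- b * sc
    }
    if (max(a, b) > 0.5 * n) stop("lesion axes exceed the image frame", call. = FALSE)
    phi <- stats::runif(1, 0, pi)
    cr <- n / 2 + stats::runif(1, -0.05, 0.05) * n
    cc <- n / 2 + stats::runif(1, -0.05, 0.05) * n
    modes <- 3:8
    amp <- stats::rnorm(length(modes), 0, 1)
    amp <- amp / max(sum(abs(amp)), 1e-9) * params$irregularity
    pha <- stats::runif(length(modes), 0, 2 * pi)
    rr <- matrix(seq_len(n), n, n) - cr
    cc_ <- matrix(seq_len(n), n, n, byrow = TRUE) - cc
    u <- cos(phi) * rr + sin(phi) * cc_
    v <- -sin(phi) * rr + cos(phi) * cc_
    theta <- atan2(v / b, u / a)
    pert <- matrix(1, n, n)
    for (m in seq_along(modes))
      pert <- pert + amp[m] * sin(modes[m] * theta + pha[m])
    mask <- (u / a)^2 + (v / b)^2 <= pert^2
    texture <- smooth_noise(n, sigma_blur = 6, rng_sd = 10)
    img[mask] <- params$lesion_mean + texture[mask]
  }
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
  if (params$n_hair > 0) img <- draw_hairs(img, params$n_hair)
  list(image = clip255(round(img)), mask = mask, label = params$class)
}

# Dark anti-aliased strokes across the frame, ~2 px wide.
draw_hairs <- function(img, n_hair, intensity = 40, width = 1.0) {
  n <- nrow(img)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (i in seq_len(n_hair)) {
    p0 <- stats::runif(2, 1, n)
    ang <- stats::runif(1, 0, pi)
    # distance to a gently curved line through p0 with normal (cos, sin)
    curve <- 8 * sin((cos(ang) * (cc - p0[2]) - sin(ang) * (rr - p0[1])) / 40)
    d <- abs(cos(ang) * (rr - p0[1]) + sin(ang) * (cc - p0[2]) + curve)
    w <- exp(-(d / width)^2)
    img <- img - intensity * w
  }
  clip255(img)
}

#' Sample a labelled feature table from the class-conditional statistics
#'
#' Each feature is drawn independently from a class-conditional Gaussian
#' with the means and standard deviations of [feature_schema()]; only hard
#' physical bounds are clipped (gray levels to [0, 255], area and perimeter
#' to be positive). Feature correlations are not modelled.
#'
#' @param n_per_class rows per class.
#' @param seed integer seed.
#' @param classes which of `"benign"`/`"malignant"` to generate.
#' @return data.frame of schema features plus `label`.
#' @export
make_feature_table <- function(n_per_class, seed = 0L,
                               classes = c("benign", "malignant")) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  sc <- feature_schema()
  rows <- list()
  for (cl in classes) {
    mu <- sc[[paste0(cl, "_mean")]]
    sd <- sc[[paste0(cl, "_sd")]]
    m <- matrix(stats::rnorm(n_per_class * nrow(sc)), n_per_class, nrow(sc))
    m <- sweep(sweep(m, 2, sd, "*"), 2, mu, "+")
    colnames(m) <- sc$name
    df <- as.data.frame(m)
    df$area <- pmax(df$area, 1)
    df$perimeter <- pmax(df$perimeter, 1)
    df$max_gray <- pmin(pmax(df$max_gray, 0), 255)
    df$min_gray <- pmin(pmax(df$min_gray, 0), 255)
    df$label <- cl
    rows[[cl]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a class-folder image dataset of synthetic lesions
#'
#' Generates `n_per_class` lesions for each class, splits them 70/30 into
#' `train/` and `test/` class folders of PNGs, writes the ground-truth masks
#' alongside, and records everything in `manifest.csv`.
#'
#' @param dir output directory; must not already contain files unless
#'   `force = TRUE`.
#' @param n_per_class images per class.
#' @param seed integer seed.
#' @param classes class names (default benign, malignant, normal).
#' @param size image side in pixels.
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest data.frame (columns file, mask, label,
#'   split).
#' @export
make_image_dataset <- function(dir, n_per_class, seed = 0L,
                               classes = c("benign", "malignant", "normal"),
                               size = 256L, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir, recursive = TRUE)) > 0 && !force)
    stop("directory not empty (use force = TRUE): ", dir, call. = FALSE)
  n_train <- round(0.7 * n_per_class)
  manifest <- list()
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      split <- if (i <= n_train) "train" else "test"
      les <- make_lesion(lesion_params(class = cl, seed = seed * 100000L + k,
                                       size = size))
      cdir <- file.path(dir, split, cl)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      mdir <- file.path(dir, "masks", cl)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(cdir, sprintf("%s_%04d.png", cl, i))
      fm <- file.path(mdir, sprintf("%s_%04d_mask.png", cl, i))
      write_image(les$image, f)
      write_image(les$mask * 255, fm)
      manifest[[k]] <- data.frame(file = f, mask = fm, label = cl, split = split)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
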