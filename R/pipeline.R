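# End-to-end pipeline: (synthetic or on-disk) images -> preprocessing ->
# maximum-entropy segmentation -> feature table -> SVM -> evaluation report,
# driven by one config object whose defaults are the package's documented
# stage defaults, with a manifest recording everything needed for an exact
# re-run.

#' Default pipeline configuration
#'
#' @param input directory of input images with a `manifest.csv` (as written
#'   by [make_image_dataset()]), or `NULL` to generate synthetic lesions.
#' @param out output directory for all artifacts.
#' @param n_per_class synthetic lesions per class when `input` is `NULL`.
#' @param filter denoising method (see [denoise()]).
#' @param hair_removal run [remove_hair()] before segmentation.
#' @param min_area,close_size segmentation refinement parameters.
#' @param levels gray levels for the texture matrices.
#' @param train_frac training fraction of the stratified split.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, out = "melascan_run", n_per_class = 10L,
                       filter = "median", hair_removal = FALSE,
                       min_area = 64L, close_size = 5L, levels = 32L,
                       train_frac = 0.7, seed = 0L) {
  structure(list(input = input, out = out, n_per_class = as.integer(n_per_class),
                 filter = filter, hair_removal = hair_removal,
                 min_area = as.integer(min_area), close_size = as.integer(close_size),
                 levels = as.integer(levels), train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' Plain YAML round-trip: every field of [run_config()] serialises to one
#' key.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full melanoma-detection pipeline
#'
#' Stages, in order: image acquisition (synthetic generation unless an input
#' directory is given), grayscale conversion and denoising (plus optional
#' hair removal), maximum-entropy segmentation, feature extraction,
#' stratified 70/30 split and RBF-SVM training, and evaluation. Every
#' artifact is written under `config$out` and recorded in `manifest.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the artifact paths, the evaluation report,
#'   the per-image segmentation table, and the trained model.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  manifest <- stage("input", {
    if (is.null(config$input)) {
      make_image_dataset(file.path(out, "images"), config$n_per_class,
                         seed = config$seed, classes = c("benign", "malignant"),
                         force = TRUE)
    } else {
      mf <- file.path(config$input, "manifest.csv")
      if (!file.exists(mf)) stop("no manifest.csv under ", config$input)
      utils::read.csv(mf, stringsAsFactors = FALSE)
    }
  })
  manifest <- manifest[manifest$label != "normal", , drop = FALSE]

  mask_dir <- file.path(out, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  seg_rows <- list(); feat_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- stage("preprocess", {
      x <- to_grayscale(read_image(manifest$file[i]))
      x <- denoise(x, method = config$filter)
      if (config$hair_removal) x <- remove_hair(x)$image
      x
    })
    seg <- stage("segment", segment_lesion(img, min_area = config$min_area,
                                           close_size = config$close_size))
    mask_path <- file.path(mask_dir, paste0(basename(manifest$file[i])))
    write_image(seg$mask * 255, mask_path)
    seg_rows[[i]] <- data.frame(file = manifest$file[i], mask = mask_path,
                                threshold = seg$threshold, entropy = seg$entropy)
    if (!any(seg$mask)) {
      warning("[segment] empty mask for ", manifest$file[i],
              "; image excluded from the feature table", call. = FALSE)
      next
    }
    feat_rows[[i]] <- stage("features", {
      fv <- extract_features(img, seg$mask, levels = config$levels)
      fv$label <- manifest$label[i]
      fv
    })
  }
  seg_table <- do.call(rbind, seg_rows)
  features <- do.call(rbind, feat_rows)
  seg_csv <- file.path(out, "segmentation.csv")
  feat_csv <- file.path(out, "features.csv")
  utils::write.csv(seg_table, seg_csv, row.names = FALSE)
  utils::write.csv(features, feat_csv, row.names = FALSE)

  eval_report <- stage("classify", {
    sp <- split_features(features, train_frac = config$train_frac,
                         seed = config$seed)
    model <- svm_train(sp$train)
    pred <- predict(model, sp$test)
    report <- per_class_report(sp$test$label, pred)
    cc <- confusion_counts(sp$test$label, pred, positive = "malignant")
    list(model = model, report = report, metrics = eval_metrics(cc),
         predictions = data.frame(truth = sp$test$label, pred = pred))
  })
  eval_csv <- file.path(out, "eval.csv")
  utils::write.csv(eval_report$report, eval_csv, row.names = FALSE)
  pred_csv <- file.path(out, "predictions.csv")
  utils::write.csv(eval_report$predictions, pred_csv, row.names = FALSE)

  artifacts <- list(segmentation = seg_csv, features = feat_csv,
                    eval = eval_csv, predictions = pred_csv, masks = mask_dir)
  jsonlite::write_json(
    list(config = unclass(config), artifacts = artifacts,
         metrics = eval_report$metrics),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(artifacts = artifacts, report = eval_report$report,
                 metrics = eval_report$metrics, segmentation = seg_table,
                 model = eval_report$model))
}
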