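# RBF-kernel SVM classification of lesion feature vectors: stratified 70/30
# split, per-feature z-score standardisation fitted on the training rows,
# then e1071's C-classification SVM with default hyperparameters.

#' Stratified train/test split
#'
#' @param table data.frame with a `label` column and at least two rows per
#'   class.
#' @param train_frac fraction of each class assigned to training (default
#'   0.7; the per-class training size is `round(train_frac * n)`).
#' @param seed integer seed making the split reproducible.
#' @return list with data.frames `train` and `test`.
#' @export
split_features <- function(table, train_frac = 0.7, seed = 0L) {
  stopifnot("label" %in% names(table))
  tab <- table(table$label)
  if (any(tab < 2L)) stop("every class needs at least 2 rows", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (lab in names(tab)) {
    idx <- which(table$label == lab)
    n_tr <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Train an RBF-kernel SVM on a labelled feature table
#'
#' Features are z-scored with parameters estimated on the training rows
#' (constant features get sd 1), then fit with an RBF-kernel SVM at library
#' defaults (no tuning).
#'
#' @param train data.frame of feature columns plus `label` (2 or more
#'   classes present).
#' @return object of class `melascan_svm` holding the feature schema,
#'   standardisation parameters, and the fitted SVM.
#' @export
svm_train <- function(train) {
  stopifnot("label" %in% names(train))
  if (length(unique(train$label)) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  feats <- setdiff(names(train), "label")
  x <- as.matrix(train[, feats, drop = FALSE])
  if (anyNA(x)) stop("training features contain missing values", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- e1071::svm(xs, factor(train$label), kernel = "radial", scale = FALSE)
  structure(list(features = feats, center = center, scale = scale, fit = fit),
            class = "melascan_svm")
}

#' Predict labels with a trained SVM
#'
#' @param object a `melascan_svm` model.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return character vector of predicted labels, one per row.
#' @export
predict.melascan_svm <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(newdata) == 0L) return(character(0))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.character(predict(object$fit, xs))
}
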