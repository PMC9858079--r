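#' Confusion matrix from label vectors
#'
#' `C[i, j]` counts items of true class `i` predicted as class `j`, with rows
#' and columns in the supplied class order.
#'
#' @param truth,predicted equal-length label vectors; every label must appear
#'   in `classes`.
#' @param classes class order; defaults to the sorted union of labels.
#' @return An integer matrix of class `confusion_matrix`.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class sensitivity, precision and overall accuracy
#'
#' From a confusion matrix `C`: per-class sensitivity (recall)
#' `100 * C[i,i] / rowSums(C)[i]`, precision (positive predictive value)
#' `100 * C[i,i] / colSums(C)[i]`, per-class misclassification rate
#' `100 - sensitivity`, and overall accuracy `100 * trace(C) / sum(C)` — all
#' in percent. A class never predicted has undefined precision, reported as
#' `NA` and flagged.
#'
#' @param cm a [confusion_matrix]; every true-class row must be non-empty.
#' @return A list of class `class_report`: `classes`, `sensitivity`,
#'   `precision`, `misclassification`, `accuracy`,
#'   `undefined_precision` (logical per class), `n`.
#' @examples
#' cm <- confusion_matrix(rep(c("a", "b"), c(41, 95)),
#'                        rep(c("a", "b", "b", "a"), c(35, 6, 87, 8)))
#' class_report(cm)
#' @export
class_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop("every true class must have at least one item", call. = FALSE)
  }
  cs <- colSums(cm)
  d <- diag(cm)
  sens <- 100 * d / rs
  prec <- ifelse(cs > 0, 100 * d / cs, NA_real_)
  structure(list(
    classes = rownames(cm),
    sensitivity = sens,
    precision = prec,
    misclassification = 100 - sens,
    accuracy = 100 * sum(d) / sum(cm),
    undefined_precision = cs == 0,
    n = sum(cm)
  ), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  df <- data.frame(
    sensitivity = sprintf("%.1f%%", x$sensitivity),
    precision = ifelse(is.na(x$precision), "undef",
                       sprintf("%.1f%%", x$precision)),
    misclassification = sprintf("%.1f%%", x$misclassification),
    row.names = x$classes
  )
  print(df)
  cat(sprintf("Overall accuracy: %.1f%% (n = %d)\n", x$accuracy, x$n))
  invisible(x)
}

#' Specify a lightweight image classifier
#'
#' The classification harness is pluggable; three reference models are
#' provided, all operating on downsampled grayscale pixel features:
#' \describe{
#'   \item{`"mlp"`}{single-hidden-layer perceptron ([nnet::nnet], softmax
#'     output), the default;}
#'   \item{`"multinom"`}{multinomial logistic regression ([nnet::multinom]);}
#'   \item{`"majority"`}{predicts the most frequent training class
#'     (chance-level baseline).}
#' }
#'
#' @param type model type.
#' @param feature_size images are resized to `feature_size x feature_size`
#'   grayscale before flattening (default 16, i.e. 256 features).
#' @param hidden hidden units for `"mlp"` (default 16).
#' @param decay weight decay for `"mlp"` (default 1e-3).
#' @param maxit optimizer iteration cap (default 300).
#' @return A list of class `model_spec`.
#' @export
classifier_spec <- function(type = c("mlp", "multinom", "majority"),
                            feature_size = 16L, hidden = 16L,
                            decay = 1e-3, maxit = 300L) {
  structure(list(type = match.arg(type), feature_size = as.integer(feature_size),
                 hidden = as.integer(hidden), decay = decay,
                 maxit = as.integer(maxit)),
            class = "model_spec")
}

# image file -> flattened grayscale feature vector
image_features <- function(path, feature_size) {
  if (!file.exists(path)) stop("image file missing: ", path, call. = FALSE)
  a <- png::readPNG(path)
  g <- if (length(dim(a)) == 3L) (a[, , 1] + a[, , 2] + a[, , 3]) / 3 else a
  small <- t(EBImage::imageData(
    EBImage::resize(EBImage::Image(t(g)), w = feature_size, h = feature_size)
  ))
  as.numeric(small)
}

manifest_features <- function(manifest, feature_size) {
  t(vapply(manifest$path, image_features, numeric(feature_size^2),
           feature_size = feature_size))
}

#' Train an image classifier on a dataset manifest
#'
#' Deterministic under a fixed seed (single-threaded, full-batch optimizer,
#' so the result does not depend on row order).
#'
#' @param train_manifest a `dataset_manifest` with at least two classes.
#' @param model_spec a [classifier_spec].
#' @param seed integer seed for weight initialization.
#' @return An object of class `wave_classifier` exposing
#'   [predict.wave_classifier].
#' @export
train_classifier <- function(train_manifest, model_spec = classifier_spec(),
                             seed = 1L) {
  stopifnot(is.data.frame(train_manifest), inherits(model_spec, "model_spec"))
  classes <- sort(unique(train_manifest$class))
  if (length(classes) < 2L && model_spec$type != "majority") {
    stop("training set must contain at least two classes", call. = FALSE)
  }
  y <- factor(train_manifest$class, levels = classes)
  fit <- NULL
  center <- NULL
  scale_ <- NULL
  if (model_spec$type == "majority") {
    tab <- table(y)
    fit <- classes[which.max(tab)]  # ties broken by class order
  } else {
    x <- manifest_features(train_manifest, model_spec$feature_size)
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    xs <- scale(x, center = center, scale = scale_)
    if (model_spec$type == "mlp") {
      fit <- with_seed(seed, nnet::nnet(
        xs, nnet::class.ind(y), size = model_spec$hidden, softmax = TRUE,
        decay = model_spec$decay, maxit = model_spec$maxit, trace = FALSE,
        MaxNWts = 100000L
      ))
    } else {
      df <- data.frame(y = y, xs)
      fit <- with_seed(seed, nnet::multinom(
        y ~ ., data = df, maxit = model_spec$maxit, trace = FALSE,
        MaxNWts = 100000L
      ))
    }
  }
  structure(list(spec = model_spec, classes = classes, fit = fit,
                 center = center, scale = scale_, seed = seed),
            class = "wave_classifier")
}

#' Predict rhythm classes for manifest rows
#'
#' @param object a `wave_classifier`.
#' @param newdata a `dataset_manifest` (paths are read from disk).
#' @param ... unused.
#' @return Character vector of predicted class labels; probability ties are
#'   broken by class order.
#' @export
predict.wave_classifier <- function(object, newdata, ...) {
  if (object$spec$type == "majority") {
    return(rep(object$fit, nrow(newdata)))
  }
  x <- manifest_features(newdata, object$spec$feature_size)
  xs <- scale(x, center = object$center, scale = object$scale)
  prob <- if (object$spec$type == "mlp") {
    p <- stats::predict(object$fit, xs)
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(xs))
    p
  } else {
    p <- stats::predict(object$fit, data.frame(xs), type = "probs")
    if (is.null(dim(p))) {
      p <- cbind(1 - p, p)  # two-class multinom returns a vector
    }
    p
  }
  object$classes[max.col(prob, ties.method = "first")]
}

#' @export
print.wave_classifier <- function(x, ...) {
  cat(sprintf("<wave_classifier %s>  classes: %s\n", x$spec$type,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Evaluate a trained classifier on a test manifest
#'
#' @param model a `wave_classifier`.
#' @param test_manifest a `dataset_manifest`; its classes must be a subset of
#'   the model's.
#' @return A list with `cm` (the [confusion_matrix]) and `report` (the
#'   [class_report]).
#' @export
evaluate <- function(model, test_manifest) {
  stopifnot(inherits(model, "wave_classifier"))
  extra <- setdiff(unique(test_manifest$class), model$classes)
  if (length(extra)) {
    stop("test classes not seen in training: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  pred <- predict(model, test_manifest)
  cm <- confusion_matrix(test_manifest$class, pred, classes = model$classes)
  list(cm = cm, report = class_report(cm))
}

#' Summarize class reports across cross-validation folds
#'
#' Mean and sample (n-1) standard deviation of macro-averaged sensitivity,
#' macro-averaged precision and overall accuracy across folds.
#'
#' @param reports list of at least two [class_report] objects.
#' @return A list of class `kfold_summary` with per-metric `mean` and `sd`.
#' @export
summarize_kfold <- function(reports) {
  if (length(reports) < 2L) {
    stop("need at least two fold reports", call. = FALSE)
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "class_report")))
  metric <- function(f) vapply(reports, f, numeric(1))
  vals <- list(
    sensitivity = metric(function(r) mean(r$sensitivity)),
    precision = metric(function(r) mean(r$precision, na.rm = TRUE)),
    accuracy = metric(function(r) r$accuracy)
  )
  structure(list(
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    k = length(reports)
  ), class = "kfold_summary")
}

#' @export
print.kfold_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation summary (mean +/- sd, %%):\n", x$k))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.2f +/- %.2f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
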