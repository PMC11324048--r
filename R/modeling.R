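## Class-weighted gradient-boosted tree classification with stratified
## cross-validation and imbalance-robust metrics (balanced accuracy,
## Cohen's kappa).

#' Training configuration
#'
#' Model hyperparameters are the boosting library's published defaults,
#' frozen here so runs are reproducible; the only deliberately set
#' parameter is the positive-class weight that counteracts class
#' imbalance.
#'
#' @param class_weight_ratio positive-class weight. `"auto"` uses
#'   n_negative / n_positive of the training labels.
#' @param n_folds number of stratified cross-validation folds.
#' @param seed master seed; fans out to fold assignment and training.
#' @param nrounds,max_depth,eta,nthread frozen model defaults.
#' @return named list.
#' @export
train_config <- function(class_weight_ratio = "auto", n_folds = 5L,
                         seed = 1L, nrounds = 100L, max_depth = 6L,
                         eta = 0.3, nthread = 1L) {
  if (!identical(class_weight_ratio, "auto")) {
    stopifnot(is.numeric(class_weight_ratio), class_weight_ratio > 0)
  }
  list(class_weight_ratio = class_weight_ratio,
       n_folds = as.integer(n_folds), seed = as.integer(seed),
       nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       eta = eta, nthread = as.integer(nthread))
}

#' Resolve the positive-class weight
#'
#' @param y binary labels (0/1).
#' @param cfg a [train_config()].
#' @return numeric weight: n_negative / n_positive when `"auto"`.
#' @export
class_weight_ratio <- function(y, cfg = train_config()) {
  if (identical(cfg$class_weight_ratio, "auto")) {
    sum(y == 0) / sum(y == 1)
  } else {
    cfg$class_weight_ratio
  }
}

.validate_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  nan_cols <- colnames(X)[apply(X, 2, function(col) any(!is.finite(col)))]
  if (length(nan_cols) > 0) {
    stop("non-finite feature values in column(s): ",
         paste(head(nan_cols), collapse = ", "))
  }
  list(X = X, y = y)
}

#' Train a class-weighted tree-ensemble classifier
#'
#' @param X numeric feature matrix (no missing values).
#' @param y binary labels, 1 = lysosomotropic (the positive class; positive
#'   Shapley contributions therefore point towards lysosomotropism).
#' @param cfg a [train_config()].
#' @return object of class `lyso_model`: the fitted booster plus feature
#'   schema and resolved configuration.
#' @export
train_classifier <- function(X, y, cfg = train_config()) {
  v <- .validate_xy(X, y)
  spw <- class_weight_ratio(v$y, cfg)
  set.seed(cfg$seed)
  dtrain <- xgboost::xgb.DMatrix(v$X, label = v$y, nthread = cfg$nthread)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                  eta = cfg$eta, scale_pos_weight = spw,
                  nthread = cfg$nthread, seed = cfg$seed),
    data = dtrain, nrounds = cfg$nrounds, verbose = 0)
  structure(list(booster = booster, schema = colnames(v$X), cfg = cfg,
                 scale_pos_weight = spw),
            class = "lyso_model")
}

#' @export
print.lyso_model <- function(x, ...) {
  cat("<lyso_model> ", length(x$schema), " features, ",
      x$cfg$nrounds, " rounds, scale_pos_weight = ",
      signif(x$scale_pos_weight, 4), "\n", sep = "")
  invisible(x)
}

#' Predict with a lyso_model
#'
#' @param object a `lyso_model`.
#' @param newdata feature matrix matching the training schema.
#' @param type `"prob"`, `"margin"` (log-odds) or `"label"` (0.5
#'   probability cutoff).
#' @param ... unused.
#' @return numeric (or integer for `"label"`) vector.
#' @export
predict.lyso_model <- function(object, newdata, type = c("prob", "margin",
                                                         "label"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$schema)) {
    stop("feature schema mismatch: expected ",
         length(object$schema), " training columns in training order")
  }
  dm <- xgboost::xgb.DMatrix(newdata, nthread = object$cfg$nthread)
  if (type == "margin") {
    return(predict(object$booster, dm, outputmargin = TRUE))
  }
  p <- predict(object$booster, dm)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Confusion matrix of binary predictions
#'
#' @param y_true,y_pred binary 0/1 vectors.
#' @return object of class `confusion_matrix`: list(tn, fp, fn, tp).
#' @export
confusion_matrix <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  structure(list(tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tp = sum(y_true == 1 & y_pred == 1)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(pred = c("0", "1"), true = c("0", "1")))
  print(m)
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; robust to class imbalance.
#'
#' @param cm a [confusion_matrix()].
#' @return value in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  if ((cm$tp + cm$fn) == 0 || (cm$tn + cm$fp) == 0) {
    stop("a true class is absent; balanced accuracy undefined")
  }
  (cm$tp / (cm$tp + cm$fn) + cm$tn / (cm$tn + cm$fp)) / 2
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predictions and truth, computed from
#' the confusion matrix marginals.
#'
#' @param cm a [confusion_matrix()].
#' @return value in \[-1, 1\]; defined as 0 (with a warning) when the
#'   expected agreement is 1.
#' @export
cohens_kappa <- function(cm) {
  n <- cm$tn + cm$fp + cm$fn + cm$tp
  stopifnot(n > 0)
  p_o <- (cm$tp + cm$tn) / n
  p_e <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
          (cm$tn + cm$fp) * (cm$tn + cm$fn)) / n^2
  if (p_e == 1) {
    warning("expected agreement is 1; kappa defined as 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified (per-fold class counts differ by at most one) via
#' caret's fold generator; a model is trained on each training split with
#' the supplied configuration and evaluated on the held-out fold.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param cfg a [train_config()].
#' @return object of class `eval_report`: per-fold metrics, their
#'   mean/sd, and the pooled out-of-fold confusion matrix.
#' @export
cross_validate <- function(X, y, cfg = train_config()) {
  v <- .validate_xy(X, y)
  if (min(table(v$y)) < cfg$n_folds) {
    stop("too few samples in a class to stratify ", cfg$n_folds, " folds")
  }
  set.seed(cfg$seed)
  folds <- caret::createFolds(factor(v$y), k = cfg$n_folds)
  per_fold <- data.frame(fold = seq_len(cfg$n_folds),
                         balanced_accuracy = NA_real_, kappa = NA_real_,
                         n_pos = NA_integer_, n_neg = NA_integer_)
  pooled_true <- integer(0)
  pooled_pred <- integer(0)
  for (k in seq_along(folds)) {
    idx <- folds[[k]]
    model <- train_classifier(v$X[-idx, , drop = FALSE], v$y[-idx], cfg)
    pred <- predict(model, v$X[idx, , drop = FALSE], type = "label")
    cm <- confusion_matrix(v$y[idx], pred)
    per_fold$balanced_accuracy[k] <- balanced_accuracy(cm)
    per_fold$kappa[k] <- cohens_kappa(cm)
    per_fold$n_pos[k] <- sum(v$y[idx] == 1)
    per_fold$n_neg[k] <- sum(v$y[idx] == 0)
    pooled_true <- c(pooled_true, v$y[idx])
    pooled_pred <- c(pooled_pred, pred)
  }
  structure(list(
    per_fold = per_fold,
    mean = c(balanced_accuracy = mean(per_fold$balanced_accuracy),
             kappa = mean(per_fold$kappa)),
    sd = c(balanced_accuracy = sd(per_fold$balanced_accuracy),
           kappa = sd(per_fold$kappa)),
    confusion = confusion_matrix(pooled_true, pooled_pred)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("balanced accuracy ", sprintf("%.3f", x$mean["balanced_accuracy"]))
  if (!is.na(x$sd["balanced_accuracy"])) {
    cat(sprintf(" +/- %.3f", x$sd["balanced_accuracy"]))
  }
  cat(" | kappa ", sprintf("%.3f", x$mean["kappa"]))
  if (!is.na(x$sd["kappa"])) cat(sprintf(" +/- %.3f", x$sd["kappa"]))
  cat("\n")
  invisible(x)
}

#' Evaluate a trained model on a held-out set
#'
#' @param model a `lyso_model`.
#' @param X_new,y_new held-out features (training schema) and labels.
#' @return an `eval_report` with a single entry; if only one true class is
#'   present the metrics are NA (flagged undefined) but the confusion
#'   matrix is still emitted.
#' @export
evaluate_holdout <- function(model, X_new, y_new) {
  pred <- predict(model, X_new, type = "label")
  cm <- confusion_matrix(y_new, pred)
  single_class <- (cm$tp + cm$fn) == 0 || (cm$tn + cm$fp) == 0
  ba <- if (single_class) NA_real_ else balanced_accuracy(cm)
  kp <- if (single_class) NA_real_ else cohens_kappa(cm)
  structure(list(
    per_fold = data.frame(fold = 1L, balanced_accuracy = ba, kappa = kp,
                          n_pos = cm$tp + cm$fn, n_neg = cm$tn + cm$fp),
    mean = c(balanced_accuracy = ba, kappa = kp),
    sd = c(balanced_accuracy = NA_real_, kappa = NA_real_),
    confusion = cm,
    metrics_undefined = single_class),
    class = "eval_report")
}
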