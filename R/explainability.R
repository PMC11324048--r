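## Model explanation: exact tree Shapley values in log-odds space, global
## importance ranking, dependence data, and the fingerprint-bit to
## substructure report that makes a fingerprint model's important bits
## chemically interpretable.

## Parse an xgboost booster into flat per-tree arrays (0-based children,
## feature indices; -1 marks leaves, whose values sit in `value`).
.parse_trees <- function(model) {
  if (!inherits(model, "lyso_model")) {
    stop("Shapley attribution requires a tree-ensemble lyso_model")
  }
  dt <- xgboost::xgb.model.dt.tree(model = model$booster)
  dt <- as.data.frame(dt)
  schema <- model$schema
  lapply(split(dt, dt$Tree), function(td) {
    td <- td[order(td$Node), , drop = FALSE]
    node_of <- function(id) as.integer(sub("^.*-", "", id))
    leaf <- td$Feature == "Leaf"
    list(
      feature = ifelse(leaf, -1L, match(td$Feature, schema) - 1L),
      left = ifelse(leaf, -1L, node_of(td$Yes)),
      right = ifelse(leaf, -1L, node_of(td$No)),
      threshold = ifelse(leaf, 0, td$Split),
      value = ifelse(leaf, td$Gain, 0),
      cover = td$Cover)
  })
}

## margin-space intercept of the booster (its base_score, stored on the
## probability scale, mapped to log-odds)
.base_margin <- function(model) {
  cfg <- xgboost::xgb.config(model$booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  bs <- as.numeric(cfg$learner$learner_model_param$base_score)
  stats::qlogis(bs)
}

#' Exact Shapley contributions of a tree-ensemble model
#'
#' Computes exact path-dependent tree Shapley values for every sample in
#' log-odds (margin) space: the background expectation follows the
#' cover-recorded training distribution down each tree, so the base value
#' is the model's expected margin over the training data. Positive
#' contributions push towards the positive (lysosomotropic) class.
#' Additivity holds to numerical precision: for every sample,
#' `base_value + sum(contributions)` equals the model margin.
#'
#' @param model a `lyso_model` (tree ensemble).
#' @param X feature matrix matching the training schema.
#' @return object of class `shap_matrix`: list with `base_value` (scalar
#'   log-odds), `contributions` (n x p matrix, training column order) and
#'   `margin` (the model's log-odds output recomputed in double
#'   precision).
#' @export
tree_shapley <- function(model, X) {
  if (!inherits(model, "lyso_model")) {
    stop("Shapley attribution requires a tree-ensemble lyso_model")
  }
  X <- as.matrix(X)
  if (!identical(colnames(X), model$schema)) {
    stop("feature schema mismatch with the trained model")
  }
  trees <- .parse_trees(model)
  res <- treeshap_cpp(trees, X)
  bm <- .base_margin(model)
  contributions <- res$contributions
  dimnames(contributions) <- list(rownames(X), model$schema)
  structure(list(base_value = res$expected + bm,
                 contributions = contributions,
                 margin = res$margin + bm),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("<shap_matrix> ", nrow(x$contributions), " samples x ",
      ncol(x$contributions), " features, base value ",
      signif(x$base_value, 4), " (log-odds)\n", sep = "")
  invisible(x)
}

#' Global feature importance from Shapley values
#'
#' Ranks features by the mean of their absolute Shapley values over all
#' samples, descending; ties break by feature (column) index.
#'
#' @param shap a [tree_shapley()] result.
#' @return data.frame: feature, mean_abs_shap, rank.
#' @export
global_importance <- function(shap) {
  m <- colMeans(abs(shap$contributions))
  ord <- order(-m, seq_along(m))
  data.frame(feature = names(m)[ord], mean_abs_shap = unname(m[ord]),
             rank = seq_along(m), stringsAsFactors = FALSE)
}

#' Feature-vs-contribution dependence data
#'
#' The raw (feature value, Shapley contribution) pairs behind a dependence
#' plot; no aggregation is applied.
#'
#' @param shap a [tree_shapley()] result.
#' @param X the feature matrix the contributions were computed for.
#' @param feature feature name.
#' @return data.frame: value, contribution (one row per sample).
#' @export
dependence_data <- function(shap, X, feature) {
  if (!feature %in% colnames(shap$contributions)) {
    stop("unknown feature: ", feature)
  }
  data.frame(value = as.numeric(X[, feature]),
             contribution = shap$contributions[, feature])
}

#' Fingerprint-bit to substructure explanation report
#'
#' For the top-k fingerprint bits by global Shapley importance, reports the
#' mean absolute contribution, the mean contribution over samples where
#' the bit is on and where it is off, and the decoded substructures (with
#' occurrence counts across the explained samples) that set the bit. Bits
#' that are off in every explained sample carry no importance and are
#' excluded.
#'
#' @param fpmat a [fingerprint_matrix()] result with tracked bit
#'   provenance.
#' @param shap a [tree_shapley()] result for the same samples.
#' @param top_k number of bits to report.
#' @return data.frame: bit, feature, mean_abs_shap, on_mean_shap,
#'   off_mean_shap, n_on, plus a list-column `substructures` (named counts
#'   of canonical substructure SMILES).
#' @export
bit_substructure_report <- function(fpmat, shap, top_k = 10) {
  if (is.null(fpmat$fingerprints) ||
      is.null(fpmat$fingerprints[[1]]$bit_info)) {
    stop("fingerprints lack bit provenance; rerun with track_bits = TRUE")
  }
  imp <- global_importance(shap)
  on_counts <- colSums(fpmat$X)
  imp <- imp[on_counts[imp$feature] > 0, , drop = FALSE]
  imp <- head(imp, top_k)
  decoded <- lapply(seq_len(nrow(imp)), function(k) {
    feat <- imp$feature[k]
    bit <- as.integer(sub("^bit_", "", feat))
    on <- fpmat$X[, feat] == 1
    subs <- character(0)
    for (fp in fpmat$fingerprints[on]) {
      info <- fp$bit_info[[as.character(bit)]]
      if (is.null(info)) next
      for (r in seq_len(nrow(info))) {
        subs <- c(subs, decode_environment(fp$mol, info[r, "atom"],
                                           info[r, "radius"]))
      }
    }
    contrib <- shap$contributions[, feat]
    list(row = data.frame(
      bit = bit, feature = feat, mean_abs_shap = imp$mean_abs_shap[k],
      on_mean_shap = mean(contrib[on]),
      off_mean_shap = if (any(!on)) mean(contrib[!on]) else NA_real_,
      n_on = sum(on), stringsAsFactors = FALSE),
      subs = c(sort(table(subs), decreasing = TRUE)))
  })
  out <- do.call(rbind, lapply(decoded, `[[`, "row"))
  out$substructures <- lapply(decoded, `[[`, "subs")
  out
}
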