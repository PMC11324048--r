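## Chemical-space diagnostics: nearest-neighbour Tanimoto similarity of a
## query set against a training set, ECDF summaries of those maxima, and
## PCA explained variance of descriptor matrices.

#' Maximum Tanimoto similarity against a training set
#'
#' For every query compound, computes its Tanimoto similarity (on-bit set
#' intersection over union) to every training compound and reports the
#' exact maximum and the nearest training neighbour. High-radius circular
#' fingerprints (radius 4) are the default structural representation for
#' this diagnostic.
#'
#' @param query_smiles,train_smiles SMILES vectors.
#' @param spec a [fingerprint_spec()].
#' @param query_ids,train_ids identifiers.
#' @return data.frame: query_id, max_tanimoto, nearest_train_id.
#' @export
max_similarity <- function(query_smiles, train_smiles,
                           spec = fingerprint_spec("circular", radius = 4L,
                                                   track_bits = FALSE),
                           query_ids = NULL, train_ids = NULL) {
  if (length(train_smiles) == 0) stop("empty training set")
  if (is.null(query_ids)) query_ids <- paste0("q", seq_along(query_smiles))
  if (is.null(train_ids)) train_ids <- paste0("t", seq_along(train_smiles))
  qfp <- lapply(parse_smiles(query_smiles), circular_fingerprint, spec = spec)
  tfp <- lapply(parse_smiles(train_smiles), circular_fingerprint, spec = spec)
  out <- data.frame(query_id = query_ids, max_tanimoto = NA_real_,
                    nearest_train_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(qfp)) {
    sims <- vapply(tfp, tanimoto, numeric(1), a = qfp[[i]])
    best <- which.max(sims)
    out$max_tanimoto[i] <- sims[best]
    out$nearest_train_id[i] <- train_ids[best]
  }
  out
}

#' Empirical cumulative distribution at the observed values
#'
#' Right-continuous ECDF sampled at the sorted observed values (no
#' binning); F at the maximum is 1.
#'
#' @param values numeric vector.
#' @return data.frame: value, F.
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0) stop("empty value vector")
  v <- sort(unique(values))
  data.frame(value = v, F = stats::ecdf(values)(v))
}

#' PCA explained-variance ratios
#'
#' Columns are z-standardized before the decomposition (otherwise
#' molecular-weight-scale columns dominate the variance); constant columns
#' are dropped.
#'
#' @param X numeric descriptor matrix.
#' @param k number of leading components.
#' @param scale standardize columns first (the default for descriptor
#'   matrices); set `FALSE` to decompose the raw covariance.
#' @return numeric vector of k explained-variance ratios, descending.
#' @export
pca_variance <- function(X, k = 3L, scale = TRUE) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (nrow(X) <= k) stop("need more samples than components")
  pc <- prcomp(X, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  if (k > sum(ev > .Machine$double.eps * max(ev) * nrow(X))) {
    stop("k exceeds the rank of the standardized matrix")
  }
  (ev / sum(ev))[seq_len(k)]
}
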