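## The Shapley kernel is exercised both through trained boosters
## (tree_shapley) and directly on hand-built tree lists (treeshap_cpp),
## where closed forms and subset enumeration are tractable.

shap_kernel <- function(trees, X) {
  lysoprofiler:::treeshap_cpp(trees, X)
}

test_that("a single-leaf ensemble contributes nothing beyond its base", {
  X <- matrix(rnorm(10 * 3), 10, 3)
  res <- shap_kernel(list(leaf_tree(0.7)), X)
  expect_true(all(res$contributions == 0))
  expect_equal(res$expected, 0.7)
  expect_equal(res$margin, rep(0.7, 10))
})

test_that("a depth-1 stump matches the one-player closed form", {
  ## single feature, single split: the only player's contribution is
  ## margin(x) minus the cover-weighted mean margin
  tr <- stump_tree(feature0 = 0L, threshold = 0, left_value = -1,
                   right_value = 2, left_cover = 30, right_cover = 10)
  X <- matrix(c(-0.5, 0.5, -2, 3), 4, 1)
  res <- shap_kernel(list(tr), X)
  expected_mean <- (30 * -1 + 10 * 2) / 40
  margins <- ifelse(X[, 1] < 0, -1, 2)
  expect_equal(res$expected, expected_mean)
  expect_equal(res$contributions[, 1], margins - expected_mean)
})

test_that("contributions match brute-force subset enumeration", {
  ## hand-built 3-feature ensemble with asymmetric covers and shared
  ## features across trees
  deep <- list(
    feature = c(0L, 1L, 2L, -1L, -1L, -1L, -1L),
    left = c(1L, 3L, 5L, -1L, -1L, -1L, -1L),
    right = c(2L, 4L, 6L, -1L, -1L, -1L, -1L),
    threshold = c(0.1, -0.4, 0.9, 0, 0, 0, 0),
    value = c(0, 0, 0, 1.5, -0.3, 0.8, -2.1),
    cover = c(100, 55, 45, 25, 30, 40, 5))
  trees <- list(deep,
                stump_tree(1L, 0.3, 0.4, -0.9, 18, 82),
                stump_tree(0L, -0.2, -1.1, 0.6, 50, 50))
  set.seed(42)
  X <- matrix(rnorm(25 * 3), 25, 3)
  res <- shap_kernel(trees, X)
  for (i in seq_len(nrow(X))) {
    phi <- brute_force_shapley(trees, X[i, ])
    expect_equal(unname(res$contributions[i, ]), phi, tolerance = 1e-10)
    ## local accuracy against the traversal margin
    expect_equal(res$expected + sum(phi), res$margin[i], tolerance = 1e-10)
  }
})

test_that("duplicated identical trees on different features share credit", {
  ## two identical stumps split on feature 1 and feature 2; samples with
  ## x1 == x2 must receive equal contributions on both features
  trees <- list(stump_tree(0L, 0, -1, 1, 50, 50),
                stump_tree(1L, 0, -1, 1, 50, 50))
  X <- cbind(c(-0.7, 0.3, 1.2), c(-0.7, 0.3, 1.2))
  res <- shap_kernel(trees, X)
  expect_equal(res$contributions[, 1], res$contributions[, 2],
               tolerance = 1e-12)
})

test_that("a feature never used by any tree gets zero contribution", {
  trees <- list(stump_tree(0L, 0, -1, 1, 40, 60))
  X <- matrix(rnorm(15 * 4), 15, 4)
  res <- shap_kernel(trees, X)
  expect_true(all(res$contributions[, 2:4] == 0))
})

test_that("tree_shapley on a trained booster satisfies additivity", {
  d <- separable_data(n = 200, seed = 8)
  model <- train_classifier(d$X, d$y, train_config(seed = 2, nrounds = 40))
  sh <- tree_shapley(model, d$X)
  err <- abs(sh$base_value + rowSums(sh$contributions) - sh$margin)
  expect_lt(max(err), 1e-6)
  ## the double-precision margin agrees with the booster's own output to
  ## its single-precision accuracy
  expect_equal(sh$margin, predict(model, d$X, type = "margin"),
               tolerance = 1e-4)
  expect_error(tree_shapley(model, d$X[, c("x2", "x1")]), "schema")
  expect_error(tree_shapley(list(not = "a model"), d$X), "tree-ensemble")
})

test_that("tree_shapley agrees with the booster's own attribution", {
  d <- separable_data(n = 150, seed = 9)
  model <- train_classifier(d$X, d$y, train_config(seed = 4, nrounds = 30))
  sh <- tree_shapley(model, d$X)
  dm <- xgboost::xgb.DMatrix(d$X, nthread = 1)
  pc <- predict(model$booster, dm, predcontrib = TRUE)
  expect_equal(unname(sh$contributions), unname(pc[, 1:2]),
               tolerance = 1e-4)
  expect_equal(sh$base_value, unname(pc[1, 3]), tolerance = 1e-4)
})

test_that("global importance ranks by mean absolute contribution", {
  sh <- structure(list(
    base_value = 0,
    contributions = matrix(c(1, -1, -0.1, 0.1, 0, 0), 2, 3,
                           dimnames = list(NULL, c("a", "b", "c")))),
    class = "shap_matrix")
  gi <- global_importance(sh)
  expect_identical(gi$feature, c("a", "b", "c"))
  expect_equal(gi$mean_abs_shap, c(1, 0.1, 0))
  ## sign flips leave the ranking unchanged
  sh$contributions <- -sh$contributions
  expect_identical(global_importance(sh)$feature, c("a", "b", "c"))
  ## all-zero matrix: ties broken by column index
  sh$contributions[] <- 0
  expect_identical(global_importance(sh)$feature, c("a", "b", "c"))
})

test_that("dependence data pairs values with contributions per sample", {
  d <- separable_data(n = 100, seed = 10)
  model <- train_classifier(d$X, d$y, train_config(seed = 2, nrounds = 20))
  sh <- tree_shapley(model, d$X)
  dd <- dependence_data(sh, d$X, "x1")
  expect_identical(nrow(dd), nrow(d$X))
  ## planted monotone effect: contribution rises with the feature
  expect_gt(cor(dd$value, dd$contribution, method = "spearman"), 0.5)
  expect_error(dependence_data(sh, d$X, "nope"), "unknown feature")
  ## constant features cannot be split on: zero contribution
  Xc <- cbind(d$X, const = 1)
  mc <- train_classifier(Xc, d$y, train_config(seed = 2, nrounds = 20))
  shc <- tree_shapley(mc, Xc)
  expect_true(all(abs(shc$contributions[, "const"]) < 1e-12))
})

test_that("bit-substructure report decodes planted substructure bits", {
  ## labels defined by the presence of a dimethylamino substituent
  cfg <- generator_config(n_compounds = 150, seed = 77)
  lib <- generate_library(cfg)
  y <- as.integer(lib$r1 == "NMe2" | lib$r2 == "NMe2")
  spec <- fingerprint_spec("circular", radius = 2, n_bits = 1024)
  fpm <- fingerprint_matrix(lib$smiles, spec, ids = lib$compound_id)
  keep <- colSums(fpm$X) > 0
  model <- train_classifier(fpm$X, y, train_config(seed = 3, nrounds = 40,
                                                   max_depth = 4))
  sh <- tree_shapley(model, fpm$X)
  rep_ <- bit_substructure_report(fpm, sh, top_k = 5)
  expect_lte(nrow(rep_), 5)
  expect_true(all(rep_$n_on > 0))
  ## every reported bit decodes to at least one substructure whose
  ## canonical form re-appears across the on-samples
  expect_true(all(vapply(rep_$substructures, length, integer(1)) > 0))
  ## the top bit for this planted label should be amine-related and push
  ## towards the positive class when on
  top <- rep_[1, ]
  expect_gt(top$on_mean_shap, 0)
  subs <- names(rep_$substructures[[1]])
  expect_true(any(grepl("N", subs)))
  ## provenance: reported substructure bits re-hash to themselves
  probe <- fpm$fingerprints[[which(y == 1)[1]]]
  info <- probe$bit_info[[as.character(top$bit)]]
  if (!is.null(info)) {
    expect_identical(environment_bit(probe$mol, info[1, "atom"],
                                     info[1, "radius"], spec),
                     as.integer(top$bit))
  }
  ## untracked fingerprints refuse to explain
  fpm2 <- fingerprint_matrix(lib$smiles[1:3],
                             fingerprint_spec("circular", 2,
                                              track_bits = FALSE))
  expect_error(bit_substructure_report(fpm2, sh), "provenance")
})
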