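## End-to-end orchestration: synthetic study (or ingested data) ->
## profile annotation -> window filtering -> MMPA and descriptor /
## fingerprint models -> Shapley explanation -> chemical-space
## diagnostics, with a reproducible run manifest.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed, fanned out to the generator and the models.
#' @param stages stages to execute, in dependency order. `"all"` expands
#'   to the full list.
#' @param generator a [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param window a [window_config()].
#' @param fp_spec a [fingerprint_spec()] for the fingerprint model.
#' @param train a [train_config()] (its seed is overridden by `seed`).
#' @param mmpa a [mmpa_config()].
#' @param holdout_fraction fraction of window compounds held out from
#'   training for the final evaluation.
#' @return named list (class `run_config`).
#' @export
run_config <- function(out_dir = tempfile("lysorun"), seed = 1L,
                       stages = "all",
                       generator = generator_config(),
                       window = window_config(),
                       fp_spec = fingerprint_spec("circular", radius = 2L),
                       train = train_config(),
                       mmpa = mmpa_config(),
                       holdout_fraction = 0.2) {
  all_stages <- c("simulate", "profiles", "filter", "mmpa", "featurize",
                  "train", "explain", "chemspace")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  generator$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, generator = generator, window = window,
                 fp_spec = fp_spec, train = train, mmpa = mmpa,
                 holdout_fraction = holdout_fraction),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the nested configurations can be overridden from a
#' YAML file with top-level blocks `generator`, `window`, `train`,
#' `fingerprint`, `mmpa` and scalars `out_dir`, `seed`, `stages`,
#' `holdout_fraction`.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (key in c("out_dir", "seed", "stages", "holdout_fraction")) {
    if (!is.null(y[[key]])) cfg[[key]] <- y[[key]]
  }
  merge_block <- function(block, target) {
    if (!is.null(y[[block]])) {
      for (k in names(y[[block]])) target[[k]] <- y[[block]][[k]]
    }
    target
  }
  cfg$generator <- merge_block("generator", cfg$generator)
  cfg$window <- merge_block("window", cfg$window)
  cfg$train <- merge_block("train", cfg$train)
  cfg$fp_spec <- merge_block("fingerprint", cfg$fp_spec)
  cfg$mmpa <- merge_block("mmpa", cfg$mmpa)
  cfg$generator$seed <- as.integer(cfg$seed)
  cfg$train$seed <- as.integer(cfg$seed)
  cfg
}

.config_hash <- function(cfg) {
  cfg$out_dir <- NULL   # hash the scientific configuration, not the paths
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes the selected stages in dependency order and writes per-stage
#' CSV/JSON outputs plus a manifest recording the seed, the configuration
#' hash and every artifact produced. A stage whose upstream output is
#' missing fails with an error naming the stage it needs.
#'
#' @param cfg a [run_config()].
#' @return the run manifest (list), invisibly; the full state is attached
#'   as attribute `state`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  state <- list()
  outputs <- list()
  need <- function(what, stage, from) {
    if (is.null(state[[what]])) {
      stop("stage '", stage, "' needs output of stage '", from,
           "'; enable it or provide the input")
    }
  }
  emit <- function(name, path) outputs[[name]] <<- path

  if ("simulate" %in% cfg$stages) {
    study <- generate_study(cfg$generator)
    state$records <- study$records
    state$ref <- study$ref
    state$profiles <- study$profiles
    p <- file.path(cfg$out_dir, "library.csv")
    write.csv(study$records, p, row.names = FALSE)
    emit("library", p)
  }

  if ("profiles" %in% cfg$stages) {
    need("profiles", "profiles", "simulate")
    pcfg <- profile_config(
      profile_dimension = cfg$generator$profile_dimension)
    state$annotations <- annotate_profiles(state$profiles, state$ref, pcfg)
    p <- file.path(cfg$out_dir, "annotations.csv")
    write_annotations_csv(state$annotations, p)
    emit("annotations", p)
  }

  if ("filter" %in% cfg$stages) {
    need("records", "filter", "simulate")
    recs <- compound_records(state$records)
    sel <- select_training_compounds(recs, cfg$window)
    state$window_records <- sel$records
    p <- file.path(cfg$out_dir, "filter_audit.csv")
    write_audit_csv(sel$audit, p)
    emit("filter_audit", p)
  }

  if ("mmpa" %in% cfg$stages) {
    need("window_records", "mmpa", "filter")
    need("annotations", "mmpa", "profiles")
    ann <- state$annotations
    lib <- state$window_records
    lib$lyso_score <- ann$lyso_score[match(lib$compound_id,
                                           ann$compound_id)]
    mmps <- index_pairs(data.frame(compound_id = lib$compound_id,
                                   smiles = lib$canonical_smiles,
                                   lyso_score = lib$lyso_score,
                                   stringsAsFactors = FALSE), cfg$mmpa)
    state$mmps <- mmps
    if (nrow(mmps) > 0) {
      state$rules <- derive_rules(mmps)
      write_mmpa_csv(mmps, state$rules,
                     file.path(cfg$out_dir, "mmps.csv"),
                     file.path(cfg$out_dir, "rules.csv"))
      emit("mmps", file.path(cfg$out_dir, "mmps.csv"))
      emit("rules", file.path(cfg$out_dir, "rules.csv"))
    }
  }

  if ("featurize" %in% cfg$stages) {
    need("window_records", "featurize", "filter")
    wr <- state$window_records
    state$descriptors <- compute_descriptors(
      wr$canonical_smiles, wr[, c("logp", "bpka1")], ids = wr$compound_id)
    state$fpmat <- fingerprint_matrix(wr$canonical_smiles, cfg$fp_spec,
                                      ids = wr$compound_id)
    p <- file.path(cfg$out_dir, "descriptors.csv")
    write.csv(state$descriptors, p)
    emit("descriptors", p)
  }

  if ("train" %in% cfg$stages) {
    need("descriptors", "train", "featurize")
    need("annotations", "train", "profiles")
    wr <- state$window_records
    ann <- state$annotations
    y <- as.integer(ann$label[match(wr$compound_id,
                                    ann$compound_id)] == "lysosomotropic")
    set.seed(cfg$seed)
    n <- nrow(wr)
    holdout <- sample(n, round(cfg$holdout_fraction * n))
    train_idx <- setdiff(seq_len(n), holdout)
    X <- state$descriptors
    state$y <- y
    state$holdout <- holdout
    state$cv <- cross_validate(X[train_idx, , drop = FALSE], y[train_idx],
                               cfg$train)
    state$model <- train_classifier(X[train_idx, , drop = FALSE],
                                    y[train_idx], cfg$train)
    state$holdout_eval <- evaluate_holdout(
      state$model, X[holdout, , drop = FALSE], y[holdout])
    metrics <- list(
      cv_mean = as.list(state$cv$mean), cv_sd = as.list(state$cv$sd),
      holdout = as.list(state$holdout_eval$mean),
      holdout_confusion = unclass(state$holdout_eval$confusion))
    p <- file.path(cfg$out_dir, "model_metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
    emit("model_metrics", p)
  }

  if ("explain" %in% cfg$stages) {
    need("model", "explain", "train")
    X <- state$descriptors
    idx <- setdiff(seq_len(nrow(X)), state$holdout)
    state$shap <- tree_shapley(state$model, X[idx, , drop = FALSE])
    state$importance <- global_importance(state$shap)
    p <- file.path(cfg$out_dir, "importance.csv")
    write.csv(state$importance, p, row.names = FALSE)
    emit("importance", p)
  }

  if ("chemspace" %in% cfg$stages) {
    need("window_records", "chemspace", "filter")
    need("descriptors", "chemspace", "featurize")
    state$pca <- pca_variance(state$descriptors[,
      colSums(is.na(state$descriptors)) == 0, drop = FALSE], k = 3)
    p <- file.path(cfg$out_dir, "pca_variance.json")
    jsonlite::write_json(as.list(setNames(state$pca, paste0("PC", 1:3))),
                         p, auto_unbox = TRUE, digits = NA)
    emit("pca", p)
  }

  manifest <- list(seed = cfg$seed, config_hash = hash,
                   stages = cfg$stages, outputs = outputs,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "state") <- state
  invisible(manifest)
}
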