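## Morphological profile scoring: Z-scored cell painting profiles,
## induction (bioactivity), Pearson biosimilarity to a reference phenotype
## and the resulting lysosomotropism annotation.

#' Default profile scoring configuration
#'
#' @param profile_dimension number of morphological features per profile.
#' @param t_z absolute Z-score above which a feature counts as significantly
#'   altered when computing induction. This cutoff is part of the upstream
#'   profiling protocol and must be stated explicitly in reports; 2.0 is the
#'   conventional two-sigma choice.
#' @param induction_threshold induction (percent) at or above which a
#'   compound is considered bioactive.
#' @param lyso_threshold lyso score at or above which a bioactive compound
#'   is annotated lysosomotropic.
#' @return a named list of configuration values.
#' @export
profile_config <- function(profile_dimension = 579L, t_z = 2.0,
                           induction_threshold = 5, lyso_threshold = 75) {
  stopifnot(profile_dimension >= 1, t_z > 0)
  list(profile_dimension = as.integer(profile_dimension), t_z = t_z,
       induction_threshold = induction_threshold,
       lyso_threshold = lyso_threshold)
}

#' Construct a compound profile
#'
#' A profile is a compound's vector of Z-scored morphological features plus
#' its induction (the percentage of significantly altered features).
#'
#' @param compound_id compound identifier.
#' @param z numeric vector of Z-scores (length must equal
#'   `cfg$profile_dimension`).
#' @param cfg a [profile_config()].
#' @param concentration optional concentration in micromolar (metadata).
#' @return an object of class `cp_profile`.
#' @export
cp_profile <- function(compound_id, z, cfg = profile_config(),
                       concentration = NA_real_) {
  z <- as.numeric(z)
  if (length(z) != cfg$profile_dimension) {
    stop("profile for ", compound_id, " has ", length(z),
         " features; expected ", cfg$profile_dimension)
  }
  structure(list(compound_id = compound_id, z = z,
                 induction = induction(z, cfg$t_z),
                 concentration = concentration),
            class = "cp_profile")
}

#' Construct a reference profile
#'
#' The reference defines the lysosomotropic phenotype that test compounds
#' are scored against (in the original assay, the profile of the reference
#' lysosomotropic agent SAG).
#'
#' @param name reference name, e.g. `"SAG-like"`.
#' @param z numeric vector of Z-scores.
#' @return an object of class `reference_profile`.
#' @export
reference_profile <- function(name, z) {
  z <- as.numeric(z)
  if (sd(z) == 0) stop("reference profile must not be constant")
  structure(list(name = name, z = z), class = "reference_profile")
}

#' Z-score raw feature tables against DMSO controls
#'
#' Each feature of a treated well is centered on the median of its DMSO
#' control wells and scaled by 1.4826 times their median absolute
#' deviation (the robust, normal-consistent analogue of mean/sd scaling).
#' Features whose control MAD is zero cannot be scaled; their Z-scores are
#' set to 0 and the feature is flagged in the attached QC report.
#'
#' @param raw_treated numeric feature-by-well matrix/data.frame of treated
#'   wells (rownames are feature names, one column per well/compound).
#' @param raw_controls numeric feature-by-well matrix of DMSO control wells
#'   with an identical ordered feature list (>= 4 control wells).
#' @param cfg a [profile_config()]; `profile_dimension` is taken from the
#'   feature list.
#' @param robust if `FALSE`, use mean/sd of the controls instead of
#'   median/scaled-MAD.
#' @return a list of [cp_profile()] objects, one per treated column, with a
#'   `qc` attribute (data.frame of flagged zero-dispersion features).
#' @export
zscore_profiles <- function(raw_treated, raw_controls,
                            cfg = profile_config(
                              profile_dimension = nrow(raw_treated)),
                            robust = TRUE) {
  raw_treated <- as.matrix(raw_treated)
  raw_controls <- as.matrix(raw_controls)
  if (nrow(raw_treated) != nrow(raw_controls) ||
      !identical(rownames(raw_treated), rownames(raw_controls))) {
    stop("treated and control tables must share an identical ordered feature list")
  }
  if (ncol(raw_controls) < 4) {
    stop("need at least 4 control wells per feature")
  }
  if (robust) {
    center <- apply(raw_controls, 1, median)
    scale_ <- apply(raw_controls, 1, mad)   # mad() already applies 1.4826
  } else {
    center <- rowMeans(raw_controls)
    scale_ <- apply(raw_controls, 1, sd)
  }
  flagged <- which(scale_ == 0)
  z <- sweep(raw_treated, 1, center, "-")
  ok <- scale_ != 0
  z[ok, ] <- sweep(z[ok, , drop = FALSE], 1, scale_[ok], "/")
  z[!ok, ] <- 0
  ids <- colnames(raw_treated)
  if (is.null(ids)) ids <- paste0("well", seq_len(ncol(raw_treated)))
  profiles <- lapply(seq_len(ncol(z)), function(j)
    cp_profile(ids[j], z[, j], cfg))
  qc <- data.frame(
    feature = if (length(flagged)) rownames(raw_treated)[flagged] else character(0),
    reason = rep("zero control dispersion; z set to 0", length(flagged)),
    stringsAsFactors = FALSE)
  attr(profiles, "qc") <- qc
  profiles
}

#' Induction: percentage of significantly altered features
#'
#' @param profile_z numeric vector of Z-scores.
#' @param t_z significance cutoff on |z|.
#' @return percent in \[0, 100\].
#' @export
induction <- function(profile_z, t_z = 2.0) {
  if (length(profile_z) == 0) stop("empty profile vector")
  stopifnot(t_z > 0)
  100 * sum(abs(profile_z) >= t_z) / length(profile_z)
}

#' Pearson biosimilarity between two profiles
#'
#' 100 times the Pearson correlation, clamped below at 0 so the score lives
#' on the 0 (no biosimilarity) to 100 (full biosimilarity) scale.
#'
#' @param a,b numeric vectors of equal length (>= 3), neither constant.
#' @return score in \[0, 100\].
#' @export
biosimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("profile dimensions differ")
  if (length(a) < 3) stop("need at least 3 features")
  if (sd(a) == 0 || sd(b) == 0) stop("constant profile: correlation undefined")
  100 * max(0, cor(a, b))
}

#' Annotate a profile for lysosomotropism
#'
#' The lyso score is the biosimilarity of the compound profile to the
#' reference profile. A compound is annotated lysosomotropic when it is
#' bioactive (induction at or above the induction threshold) and its lyso
#' score reaches the lyso threshold. Non-bioactive compounds are annotated
#' non-lysosomotropic regardless of correlation (a near-flat profile's
#' correlation is noise) and flagged as inactive.
#'
#' @param profile a [cp_profile()].
#' @param ref a [reference_profile()].
#' @param cfg a [profile_config()].
#' @return a one-row data.frame: compound_id, induction, lyso_score, label,
#'   bioactive, inactive.
#' @export
annotate_lysosomotropism <- function(profile, ref, cfg = profile_config()) {
  if (length(profile$z) != length(ref$z)) {
    stop("profile and reference dimensions differ")
  }
  score <- if (sd(profile$z) == 0) 0 else biosimilarity(profile$z, ref$z)
  bioactive <- profile$induction >= cfg$induction_threshold
  lyso <- bioactive && score >= cfg$lyso_threshold
  data.frame(
    compound_id = profile$compound_id,
    induction = profile$induction,
    lyso_score = score,
    label = if (lyso) "lysosomotropic" else "non_lysosomotropic",
    bioactive = bioactive,
    inactive = !bioactive,
    stringsAsFactors = FALSE)
}

#' Annotate a list of profiles
#'
#' @param profiles list of [cp_profile()] objects.
#' @param ref a [reference_profile()].
#' @param cfg a [profile_config()].
#' @return data.frame with one row per profile (see
#'   [annotate_lysosomotropism()]).
#' @export
annotate_profiles <- function(profiles, ref, cfg = profile_config()) {
  do.call(rbind, lapply(profiles, annotate_lysosomotropism, ref = ref,
                        cfg = cfg))
}

#' Read profiles from CSV
#'
#' Expects one row per compound: a `compound_id` column followed by feature
#' columns (optionally restricted by a sidecar feature manifest).
#'
#' @param path CSV path.
#' @param cfg a [profile_config()]; dimension defaults to the number of
#'   feature columns found.
#' @param manifest optional path to a text file listing feature column
#'   names, one per line.
#' @return list of [cp_profile()] objects.
#' @export
read_profiles_csv <- function(path, cfg = NULL, manifest = NULL) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot("compound_id" %in% names(df))
  feats <- setdiff(names(df), "compound_id")
  if (!is.null(manifest)) {
    want <- readLines(manifest)
    missing <- setdiff(want, feats)
    if (length(missing)) stop("features in manifest absent from CSV: ",
                              paste(head(missing), collapse = ", "))
    feats <- want
  }
  if (is.null(cfg)) cfg <- profile_config(profile_dimension = length(feats))
  lapply(seq_len(nrow(df)), function(i)
    cp_profile(df$compound_id[i], as.numeric(df[i, feats]), cfg))
}

#' Write lysosomotropism annotations to CSV
#'
#' @param annotations data.frame from [annotate_profiles()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
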