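## Compound selection: the training-set filtering cascade and the
## external-set standardization, both with per-stage audit trails, plus the
## physicochemical window test (log P and strongest basic pKa) that defines
## where lysosomotropism is physicochemically plausible.

#' Physicochemical window configuration
#'
#' Defaults follow the lysosomotropism window: log P strictly greater than
#' 2 and strongest basic pKa strictly between 6.2 and 11 (the literature
#' bound of 6.5 lowered to 6.2 to keep borderline basic compounds).
#'
#' @param logp_min lower bound on log P (strict).
#' @param bpka_min,bpka_max bounds on basic pKa (strict).
#' @return named list.
#' @export
window_config <- function(logp_min = 2, bpka_min = 6.2, bpka_max = 11) {
  stopifnot(bpka_min < bpka_max)
  list(logp_min = logp_min, bpka_min = bpka_min, bpka_max = bpka_max)
}

#' Test membership in the physicochemical window
#'
#' All three comparisons are strict. A missing basic pKa means the compound
#' has no basic center in the relevant range and is outside the window.
#'
#' @param logp numeric vector of log P values.
#' @param bpka1 numeric vector of strongest basic pKa values (NA allowed).
#' @param cfg a [window_config()].
#' @return logical vector.
#' @export
in_physchem_window <- function(logp, bpka1, cfg = window_config()) {
  ok <- !is.na(logp) & !is.na(bpka1) &
    logp > cfg$logp_min & bpka1 > cfg$bpka_min & bpka1 < cfg$bpka_max
  ok
}

#' Assemble a compound record table
#'
#' Validates and completes a table of compound records: parses SMILES,
#' canonicalizes them and fills in heavy-atom counts. Rows whose structure
#' does not parse are moved to a rejects table (attribute `rejects`).
#'
#' @param df data.frame with columns `compound_id`, `smiles`, `logp`,
#'   `bpka1`, and optionally `concentration`, `toxic_flag`, `purity_alert`.
#'   Acidic pKa columns (`apka1`, `apka2`), if present, are dropped as
#'   redundant for this analysis.
#' @return data.frame of parsed records with `canonical_smiles` and
#'   `heavy_atom_count` columns; rejects as attribute.
#' @export
compound_records <- function(df) {
  stopifnot(all(c("compound_id", "smiles") %in% names(df)))
  df <- df[, setdiff(names(df), c("apka1", "apka2")), drop = FALSE]
  for (col in c("logp", "bpka1")) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"concentration" %in% names(df)) df$concentration <- 10
  if (!"toxic_flag" %in% names(df)) df$toxic_flag <- FALSE
  if (!"purity_alert" %in% names(df)) df$purity_alert <- FALSE
  can <- canonical_smiles(df$smiles)
  ok <- !is.na(can)
  rejects <- df[!ok, , drop = FALSE]
  df <- df[ok, , drop = FALSE]
  df$canonical_smiles <- can[ok]
  df$heavy_atom_count <- heavy_atom_count(df$canonical_smiles)
  attr(df, "rejects") <- rejects
  df
}

.audit_stage <- function(name, n_in, n_out) {
  data.frame(stage_name = name, n_in = n_in, n_removed = n_in - n_out,
             n_out = n_out, stringsAsFactors = FALSE)
}

#' Select compounds for training
#'
#' Applies the training-set filtering cascade in order: measured at the 10
#' micromolar screening concentration; not toxic; no purity alert; heavy
#' atom count at most 50; log P and basic pKa values present; inside the
#' physicochemical window. Returns the survivors plus a per-stage audit
#' trail (n_in / n_removed / n_out per stage).
#'
#' @param records data.frame from [compound_records()].
#' @param cfg a [window_config()].
#' @param concentration required assay concentration (micromolar).
#' @param max_heavy_atoms heavy-atom cap.
#' @return list with elements `records` (survivors) and `audit`
#'   (data.frame of filter stages).
#' @export
select_training_compounds <- function(records, cfg = window_config(),
                                      concentration = 10,
                                      max_heavy_atoms = 50) {
  audit <- list()
  cur <- records
  step <- function(name, keep) {
    n_in <- nrow(cur)
    nxt <- cur[keep, , drop = FALSE]
    audit[[length(audit) + 1]] <<- .audit_stage(name, n_in, nrow(nxt))
    cur <<- nxt
  }
  step("concentration_10uM", cur$concentration == concentration)
  step("not_toxic", !cur$toxic_flag)
  step("no_purity_alert", !cur$purity_alert)
  step("heavy_atoms_le_50", cur$heavy_atom_count <= max_heavy_atoms)
  step("logp_bpka_present", !is.na(cur$logp) & !is.na(cur$bpka1))
  step("physchem_window", in_physchem_window(cur$logp, cur$bpka1, cfg))
  list(records = cur, audit = do.call(rbind, audit))
}

#' Standardize an external compound set
#'
#' Pipeline used for vendor libraries before prediction: heavy-atom count
#' between `min_heavy_atoms` and `max_heavy_atoms` (inclusive),
#' canonicalization, duplicate removal by canonical structure, removal of
#' compounds already present in the training set, physicochemical window,
#' and an optional promiscuity/frequent-hitter SMARTS blocklist supplied by
#' the caller (catalogs such as NIBR/PAINS are versioned external artifacts
#' and are plugged in rather than baked in).
#'
#' @param records data.frame from [compound_records()].
#' @param cfg a [window_config()].
#' @param training_smiles character vector of training-set SMILES to
#'   exclude (canonicalized internally).
#' @param min_heavy_atoms,max_heavy_atoms inclusive heavy-atom bounds.
#' @param promiscuity_smarts optional character vector of SMARTS; any match
#'   removes the compound.
#' @return list with `records` and `audit` as in
#'   [select_training_compounds()].
#' @export
standardize_external <- function(records, cfg = window_config(),
                                 training_smiles = character(0),
                                 min_heavy_atoms = 20, max_heavy_atoms = 50,
                                 promiscuity_smarts = NULL) {
  audit <- list()
  cur <- records
  step <- function(name, keep) {
    n_in <- nrow(cur)
    nxt <- cur[keep, , drop = FALSE]
    audit[[length(audit) + 1]] <<- .audit_stage(name, n_in, nrow(nxt))
    cur <<- nxt
  }
  step("heavy_atom_range",
       cur$heavy_atom_count >= min_heavy_atoms &
       cur$heavy_atom_count <= max_heavy_atoms)
  step("deduplicate", !duplicated(cur$canonical_smiles))
  train_can <- unique(canonical_smiles(training_smiles))
  step("training_overlap", !(cur$canonical_smiles %in% train_can))
  step("physchem_window", in_physchem_window(cur$logp, cur$bpka1, cfg))
  if (!is.null(promiscuity_smarts) && length(promiscuity_smarts) > 0 &&
      nrow(cur) > 0) {
    sdfset <- .smiles_to_sdfset(cur$canonical_smiles, cur$compound_id)
    hit <- rep(FALSE, nrow(cur))
    for (sm in promiscuity_smarts) {
      cnt <- ChemmineR::smartsSearchOB(sdfset, sm, uniqueMatches = TRUE)
      hit <- hit | (cnt > 0)
    }
    step("promiscuity_smarts", !hit)
  }
  list(records = cur, audit = do.call(rbind, audit))
}

#' Write a filter audit trail to CSV
#'
#' @param audit audit data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_audit_csv <- function(audit, path) {
  write.csv(audit, path, row.names = FALSE)
  invisible(path)
}
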