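## Synthetic study generator.
##
## Emulates the structure of a lysosomotropism screening campaign without
## any proprietary data: a scaffold x substituent combinatorial library
## (guaranteeing matched molecular pairs), externally-supplied-style log P
## and basic pKa values from additive group contributions plus noise, a
## planted logistic lysosomotropism mechanism in (log P, bpKa, TPSA, MW),
## and 579-feature morphological profiles whose Pearson correlation to a
## reference phenotype encodes the planted label.

.SYN_SUBSTITUENTS <- data.frame(
  name = c("H", "Me", "Et", "nPr", "iPr", "tBu", "F", "Cl", "Br", "OH",
           "OMe", "OEt", "NH2", "NMe2", "CN", "NO2", "CF3", "CONH2",
           "COOMe", "SO2Me", "Ac"),
  smiles = c("", "C", "CC", "CCC", "C(C)C", "C(C)(C)C", "F", "Cl", "Br",
             "O", "OC", "OCC", "N", "N(C)C", "C#N", "[N+](=O)[O-]",
             "C(F)(F)F", "C(=O)N", "C(=O)OC", "S(C)(=O)=O", "C(=O)C"),
  logp_inc = c(0, 0.56, 1.02, 1.55, 1.53, 1.98, 0.14, 0.71, 0.86, -0.67,
               -0.02, 0.38, -1.23, 0.18, -0.57, -0.28, 0.88, -1.49,
               -0.01, -1.63, -0.55),
  bpka_shift = c(0, 0.05, 0.05, 0.05, 0.05, 0.05, -0.15, -0.2, -0.2,
                 -0.2, 0.1, 0.1, 0.1, 0.15, -0.55, -0.7, -0.4, -0.45,
                 -0.35, -0.6, -0.35),
  stringsAsFactors = FALSE)

.SYN_SCAFFOLDS <- data.frame(
  name = c("methylpiperazine_phenyl", "diethylaminoethoxy_phenyl",
           "dimethylaminopropyl_phenyl", "piperidinylethyl_phenyl",
           "methylpiperidinyloxy_phenyl", "pyrrolidinylmethyl_phenyl",
           "morpholinoethyl_phenyl", "benzylpiperazine",
           "benzanilide", "aryl_sulfonamide", "diaryl_ether",
           "phenyl_urea"),
  template = c(
    "CN1CCN(CC1)c1cc({R2})cc({R1})c1",
    "CCN(CC)CCOc1cc({R2})cc({R1})c1",
    "CN(C)CCCc1cc({R2})cc({R1})c1",
    "C1CCN(CC1)CCc1cc({R2})cc({R1})c1",
    "CN1CCC(CC1)Oc1cc({R2})cc({R1})c1",
    "C1CCN(C1)Cc1cc({R2})cc({R1})c1",
    "O1CCN(CC1)CCc1cc({R2})cc({R1})c1",
    "C1CN(CCN1C)Cc1cc({R2})cc({R1})c1",
    "O=C(Nc1ccc({R2})cc1)c1ccc({R1})cc1",
    "O=S(=O)(NC)c1cc({R2})cc({R1})c1",
    "c1ccc(Oc2cc({R2})cc({R1})c2)cc1",
    "O=C(NC)Nc1cc({R2})cc({R1})c1"),
  logp_base = c(2.4, 3.0, 2.7, 3.3, 2.9, 2.6, 2.2, 2.5, 2.9, 1.7, 3.6,
                2.0),
  bpka_base = c(7.9, 8.9, 9.6, 9.9, 8.5, 9.2, 6.9, 8.2, NA, NA, NA, NA),
  stringsAsFactors = FALSE)

## aniline-type amine substituents get a weak basic pKa on otherwise
## non-basic scaffolds (outside the window by design)
.ANILINE_SUBS <- c("NH2", "NMe2")
.ANILINE_BPKA <- 4.6

#' Synthetic study configuration
#'
#' The defaults are the study conditions every other module is exercised
#' under: a 65/35 non-lysosomotropic/lysosomotropic split among window
#' compounds, a logistic mechanism rewarding lipophilicity, basicity and
#' molecular weight and penalizing polar surface area, and profile
#' correlation bands that separate lysosomotropic (0.75-0.98) from
#' non-lysosomotropic (-0.2-0.6) phenotypes.
#'
#' @param n_compounds library size.
#' @param seed master seed; every stochastic step derives its stream from
#'   it, so a configuration generates a byte-identical study.
#' @param scaffolds,substituents data.frames defining the combinatorial
#'   library (templates with `{R1}`/`{R2}` sites; substituent fragments
#'   with additive log P increments and basic pKa shifts).
#' @param beta named coefficients of the planted logistic mechanism:
#'   intercept `b0`, then per-unit effects of (log P - 2), (bpKa - 6.2),
#'   TPSA/100 (entering negatively) and MW/100.
#' @param noise_sd Gaussian noise added to the group-contribution log P
#'   (and, scaled by 5/3, to bpKa).
#' @param band_lyso,band_nonlyso target Pearson-correlation bands of the
#'   generated profiles to the reference phenotype.
#' @param profile_dimension number of morphological features.
#' @param amp_active,amp_inactive marginal Z-score standard deviation of
#'   bioactive and inactive profiles (with the conventional |z| >= 2
#'   significance cutoff, 2.2 gives inductions around 35, 0.5 gives
#'   inductions near 0).
#' @param frac_bioactive_nonlyso fraction of non-lysosomotropic compounds
#'   that are nonetheless bioactive (distinct phenotype, profile drawn
#'   against latent vectors orthogonal to the reference).
#' @param frac_offconc,frac_toxic,frac_purity small fractions of records
#'   planted with off-concentration measurements, toxicity flags and
#'   purity alerts, so filter stages have work to do.
#' @return named list (class `generator_config`).
#' @export
generator_config <- function(n_compounds = 2000L, seed = 20260928L,
                             scaffolds = .SYN_SCAFFOLDS,
                             substituents = .SYN_SUBSTITUENTS,
                             beta = c(b0 = -8.5, logp = 2.0, bpka = 1.3,
                                      tpsa = 2.5, mw = 0.8),
                             noise_sd = 0.15,
                             band_lyso = c(0.75, 0.98),
                             band_nonlyso = c(-0.2, 0.6),
                             profile_dimension = 579L,
                             amp_active = 2.2, amp_inactive = 0.5,
                             frac_bioactive_nonlyso = 0.35,
                             frac_offconc = 0.02, frac_toxic = 0.02,
                             frac_purity = 0.02) {
  if (nrow(substituents) == 0) stop("empty substituent alphabet")
  structure(list(
    n_compounds = as.integer(n_compounds), seed = as.integer(seed),
    scaffolds = scaffolds, substituents = substituents, beta = beta,
    noise_sd = noise_sd, band_lyso = band_lyso,
    band_nonlyso = band_nonlyso,
    profile_dimension = as.integer(profile_dimension),
    amp_active = amp_active, amp_inactive = amp_inactive,
    frac_bioactive_nonlyso = frac_bioactive_nonlyso,
    frac_offconc = frac_offconc, frac_toxic = frac_toxic,
    frac_purity = frac_purity), class = "generator_config")
}

.instantiate_template <- function(template, r1, r2) {
  sub1 <- ifelse(nzchar(r1), paste0("(", r1, ")"), "")
  sub2 <- ifelse(nzchar(r2), paste0("(", r2, ")"), "")
  out <- template
  for (i in seq_along(out)) {
    out[i] <- gsub("\\(\\{R1\\}\\)", sub1[i], out[i])
    out[i] <- gsub("\\(\\{R2\\}\\)", sub2[i], out[i])
  }
  out
}

#' Generate a synthetic compound library
#'
#' Samples unique scaffold x substituent combinations, instantiates their
#' SMILES, and assigns log P (group contribution plus Gaussian noise),
#' basic pKa (for amine-bearing compounds; missing otherwise),
#' concentration and quality flags. Deterministic under the configured
#' seed.
#'
#' @param cfg a [generator_config()].
#' @return data.frame of compound records: compound_id, smiles, scaffold,
#'   r1, r2, logp, bpka1, concentration, toxic_flag, purity_alert.
#' @export
generate_library <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  sc <- cfg$scaffolds
  su <- cfg$substituents
  two_site <- grepl("\\{R2\\}", sc$template[1])
  grid <- expand.grid(scaffold = seq_len(nrow(sc)), r1 = seq_len(nrow(su)),
                      r2 = seq_len(nrow(su)))
  ## drop symmetric duplicates within a scaffold (R1/R2 sites are
  ## topologically distinct in the templates, but identical substituent
  ## pairs in swapped order still duplicate whenever sites are equivalent;
  ## canonical-SMILES dedup below is the real guard)
  if (nrow(grid) < cfg$n_compounds) {
    stop("requested more compounds than the combinatorial space holds")
  }
  pick <- sample(nrow(grid), nrow(grid))  # random order, then take unique
  grid <- grid[pick, , drop = FALSE]
  smiles <- .instantiate_template(sc$template[grid$scaffold],
                                  su$smiles[grid$r1], su$smiles[grid$r2])
  ## canonicalize lazily, chunk by chunk, until n unique structures found
  can <- character(0)
  keep_rows <- integer(0)
  seen <- character(0)
  pos <- 0L
  chunk <- max(256L, cfg$n_compounds)
  while (length(keep_rows) < cfg$n_compounds && pos < nrow(grid)) {
    take <- seq(pos + 1L, min(pos + chunk, nrow(grid)))
    cc <- canonical_smiles(smiles[take])
    ok <- !is.na(cc) & !duplicated(cc) & !(cc %in% seen)
    keep_rows <- c(keep_rows, take[ok])
    can <- c(can, cc[ok])
    seen <- c(seen, cc[ok])
    pos <- pos + length(take)
  }
  if (length(keep_rows) < cfg$n_compounds) {
    stop("combinatorial space too small after deduplication")
  }
  grid <- grid[keep_rows[seq_len(cfg$n_compounds)], , drop = FALSE]
  can <- can[seq_len(cfg$n_compounds)]
  n <- nrow(grid)
  logp <- sc$logp_base[grid$scaffold] + su$logp_inc[grid$r1] +
    su$logp_inc[grid$r2] + rnorm(n, 0, cfg$noise_sd)
  bpka <- sc$bpka_base[grid$scaffold]
  aniline <- is.na(bpka) & (su$name[grid$r1] %in% .ANILINE_SUBS |
                            su$name[grid$r2] %in% .ANILINE_SUBS)
  bpka[aniline] <- .ANILINE_BPKA
  shift <- su$bpka_shift[grid$r1] + su$bpka_shift[grid$r2]
  has_b <- !is.na(bpka)
  bpka[has_b] <- pmin(12, pmax(5, bpka[has_b] + shift[has_b] +
                                 rnorm(sum(has_b), 0, cfg$noise_sd * 5 / 3)))
  concentration <- rep(10, n)
  off <- runif(n) < cfg$frac_offconc
  concentration[off] <- sample(c(30, 50), sum(off), replace = TRUE)
  data.frame(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = can,
    scaffold = sc$name[grid$scaffold],
    r1 = su$name[grid$r1], r2 = su$name[grid$r2],
    logp = logp, bpka1 = bpka,
    concentration = concentration,
    toxic_flag = runif(n) < cfg$frac_toxic,
    purity_alert = runif(n) < cfg$frac_purity,
    stringsAsFactors = FALSE)
}

## TPSA and molecular weight needed by the planted mechanism
.tpsa_mw <- function(smiles) {
  mols <- parse_smiles(smiles)
  mw <- vapply(mols, .mol_weight, numeric(1))
  sdfset <- .smiles_to_sdfset(vapply(mols, `[[`, character(1), "smiles"))
  tpsa <- ChemmineR::propOB(sdfset)$TPSA
  data.frame(tpsa = tpsa, mw = mw)
}

#' Plant lysosomotropism labels
#'
#' The planted mechanism is a logistic model in the properties the
#' phenomenon is physicochemically driven by: probability increases with
#' log P above 2, basic pKa above 6.2 and molecular weight, and decreases
#' with topological polar surface area. Compounds without a basic center
#' (missing bpKa) get probability (numerically) zero. Labels are Bernoulli
#' draws from the latent probability, deterministic under the seed.
#'
#' @param records data.frame from [generate_library()].
#' @param cfg a [generator_config()].
#' @return `records` with added columns tpsa, mw, latent_p, lyso_label
#'   (0/1).
#' @export
plant_labels <- function(records, cfg = generator_config()) {
  pm <- .tpsa_mw(records$smiles)
  b <- cfg$beta
  lp <- b[["b0"]] + b[["logp"]] * (records$logp - 2) +
    b[["bpka"]] * (ifelse(is.na(records$bpka1), 0, records$bpka1) - 6.2) -
    b[["tpsa"]] * pm$tpsa / 100 + b[["mw"]] * pm$mw / 100
  lp[is.na(records$bpka1)] <- -30   # no basic center: never lysosomotropic
  p <- plogis(lp)
  set.seed(cfg$seed + 1L)
  records$tpsa <- pm$tpsa
  records$mw <- pm$mw
  records$latent_p <- p
  records$lyso_label <- rbinom(nrow(records), 1L, p)
  records
}

#' Reference phenotype profile
#'
#' A fixed pseudo-random unit-variance vector derived from the master
#' seed, standing in for the measured profile of a reference
#' lysosomotropic agent.
#'
#' @param cfg a [generator_config()].
#' @return a [reference_profile()].
#' @export
make_reference_profile <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 2L)
  z <- rnorm(cfg$profile_dimension)
  reference_profile("SAG-like-synthetic", (z - mean(z)) / sd(z))
}

.unit_center <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

.orthogonalize <- function(v, basis) {
  for (b in basis) v <- v - sum(v * b) * b
  .unit_center(v)
}

#' Generate morphological profiles encoding planted labels
#'
#' Lysosomotropic compounds receive profiles whose Pearson correlation to
#' the reference is drawn from the lysosomotropic band; bioactive
#' non-lysosomotropic compounds correlate with latent alternative
#' phenotype vectors orthogonalized against the reference (with a
#' reference correlation drawn from the non-lysosomotropic band); the
#' remaining compounds are low-amplitude noise with induction below the
#' bioactivity threshold. The construction is exact: the empirical
#' correlation to the reference equals the drawn target.
#'
#' @param records data.frame from [plant_labels()].
#' @param ref a [reference_profile()].
#' @param cfg a [generator_config()].
#' @return list of [cp_profile()] objects, one per record.
#' @export
generate_profiles <- function(records, ref, cfg = generator_config()) {
  n_feat <- cfg$profile_dimension
  stopifnot(length(ref$z) == n_feat)
  set.seed(cfg$seed + 3L)
  u_ref <- .unit_center(ref$z)
  latents <- lapply(1:3, function(i)
    .orthogonalize(rnorm(n_feat), list(u_ref)))
  pcfg <- profile_config(profile_dimension = n_feat)
  scale_active <- cfg$amp_active * sqrt(n_feat)
  profiles <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    lyso <- records$lyso_label[i] == 1L
    if (lyso) {
      a <- runif(1, cfg$band_lyso[1], cfg$band_lyso[2])
      e <- .orthogonalize(rnorm(n_feat), list(u_ref))
      z <- scale_active * (a * u_ref + sqrt(1 - a^2) * e)
    } else if (runif(1) < cfg$frac_bioactive_nonlyso) {
      a <- runif(1, cfg$band_nonlyso[1], cfg$band_nonlyso[2])
      v <- latents[[sample.int(3, 1)]]
      e <- .orthogonalize(rnorm(n_feat), list(u_ref, v))
      w <- 0.7 * v + sqrt(1 - 0.7^2) * e   # unit, orthogonal to u_ref
      z <- scale_active * (a * u_ref + sqrt(1 - a^2) * w)
    } else {
      z <- rnorm(n_feat, 0, cfg$amp_inactive)
    }
    profiles[[i]] <- cp_profile(records$compound_id[i], z, pcfg)
  }
  profiles
}

#' Generate a complete synthetic study
#'
#' Library, planted labels, reference phenotype and profiles in one call,
#' with a manifest recording the generating conditions.
#'
#' @param cfg a [generator_config()].
#' @return list: records (with planted labels), ref, profiles,
#'   annotations (profile-derived lysosomotropism annotations), manifest.
#' @export
generate_study <- function(cfg = generator_config()) {
  records <- plant_labels(generate_library(cfg), cfg)
  ref <- make_reference_profile(cfg)
  profiles <- generate_profiles(records, ref, cfg)
  annotations <- annotate_profiles(
    profiles, ref, profile_config(profile_dimension = cfg$profile_dimension))
  manifest <- list(seed = cfg$seed, n_compounds = cfg$n_compounds,
                   beta = as.list(cfg$beta),
                   band_lyso = cfg$band_lyso,
                   band_nonlyso = cfg$band_nonlyso,
                   generated = nrow(records))
  list(records = records, ref = ref, profiles = profiles,
       annotations = annotations, manifest = manifest)
}
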