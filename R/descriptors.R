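## Curated "intuitive" molecular descriptors.
##
## Continuous descriptors (TPSA, H-bond counts, molar refractivity) come
## from OpenBabel; graph-derived counts (heavy atoms, rings, sp3 carbon
## fraction, rotatable bonds) are computed on the internal graph; fr_*
## functional-group counts are SMARTS-based group counters in the style of
## the familiar fragment-descriptor catalogs. Surface-partition descriptors
## of the PEOE_VSA / VSA_EState / SMR_VSA families are deliberately not
## offered: they are the canonical examples of unintuitive descriptors and
## the allowlist validator rejects them by name.

.FR_SMARTS <- c(
  fr_NH2 = "[NX3;H2;!$(NC=[!#6]);!$(NC#[!#6])]",
  fr_NH1 = "[NX3;H1;!$(NC=[!#6]);!$(NC#[!#6])]",
  fr_NH0 = "[NX3;H0;!$(NC=[!#6]);!$(NC#[!#6])]",
  fr_quatN = "[NX4+]",
  fr_nitro = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  fr_nitrile = "[NX1]#[CX2]",
  fr_halogen = "[F,Cl,Br,I]",
  fr_alkyl_halide = "[CX4][F,Cl,Br,I]",
  fr_ether = "[OD2]([#6])[#6]",
  fr_methoxy = "[OX2](-[#6])-[CH3]",
  fr_ester = "[#6][CX3](=O)[OX2H0][#6]",
  fr_amide = "[CX3](=[OX1])[NX3]",
  fr_ketone = "[#6][CX3](=[OX1])[#6]",
  fr_aldehyde = "[CX3H1](=O)[#6]",
  fr_COO = "[CX3](=O)[OX1H0-,OX2H1]",
  fr_Al_OH = "[OX2H][CX4]",
  fr_Ar_OH = "[OX2H][c]",
  fr_phenol = "[OX2H][cX3]:[c]",
  fr_aniline = "[NX3][c]",
  fr_Ar_N = "[nX2,nX3]",
  fr_pyridine = "c1ccncc1",
  fr_imidazole = "c1cnc[nH]1",
  fr_piperazine = "N1CCNCC1",
  fr_piperdine = "N1CCCCC1",
  fr_morpholine = "O1CCNCC1",
  fr_benzene = "c1ccccc1",
  fr_furan = "o1cccc1",
  fr_thiophene = "s1cccc1",
  fr_sulfide = "[SX2]([#6])[#6]",
  fr_sulfonamd = "[SX4](=[OX1])(=[OX1])[NX3]",
  fr_SH = "[SX2H]",
  fr_urea = "[NX3][CX3](=[OX1])[NX3]",
  fr_guanido = "[NX3][CX3](=[NX2])[NX3]",
  fr_azo = "[NX2]=[NX2]",
  fr_alkyne = "[CX2]#[CX2]",
  fr_CF3 = "[CX4](F)(F)F"
)

.OB_DESCRIPTORS <- c(TPSA = "TPSA", NumHAcceptors = "HBA1",
                     NumHDonors = "HBD", MolMR = "MR")

.GRAPH_DESCRIPTORS <- c("MolWt", "HeavyAtomMolWt", "HeavyAtomCount",
                        "RingCount", "FractionCSP3", "NumHeteroatoms",
                        "NOCount", "NHOHCount", "NumRotatableBonds")

.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' The default descriptor allowlist
#'
#' @return character vector of descriptor names available by default
#'   (continuous descriptors, graph counts and fr_* group counts). The two
#'   externally supplied columns `logp` and `bpka1` are appended by
#'   [compute_descriptors()] and are not part of the allowlist.
#' @export
default_descriptor_allowlist <- function() {
  c(names(.OB_DESCRIPTORS), .GRAPH_DESCRIPTORS, names(.FR_SMARTS))
}

.validate_allowlist <- function(allowlist) {
  banned <- grepl("^(PEOE_VSA|VSA_EState|SMR_VSA)", allowlist)
  if (any(banned)) {
    stop("surface-partition descriptors are excluded from the allowlist: ",
         paste(allowlist[banned], collapse = ", "))
  }
  unknown <- setdiff(allowlist, default_descriptor_allowlist())
  if (length(unknown) > 0) {
    stop("unknown descriptor(s) in allowlist: ",
         paste(unknown, collapse = ", "))
  }
  allowlist
}

.graph_descriptors <- function(g) {
  carbons <- g$elem == "C"
  sp3 <- if (any(carbons)) {
    has_multiple <- rep(FALSE, g$n)
    if (nrow(g$bonds) > 0) {
      multi <- g$bonds[g$bonds[, 3] > 1L, , drop = FALSE]
      has_multiple[unique(c(multi[, 1], multi[, 2]))] <- TRUE
    }
    sum(carbons & !has_multiple) / sum(carbons)
  } else 0
  n_components <- if (nrow(g$bonds) > 0) {
    ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
    igraph::components(ig)$no
  } else g$n
  c(MolWt = .mol_weight(g),
    HeavyAtomMolWt = .mol_weight(g, heavy_only = TRUE),
    HeavyAtomCount = g$n,
    RingCount = nrow(g$bonds) - g$n + n_components,
    FractionCSP3 = sp3,
    NumHeteroatoms = sum(!g$elem %in% c("C", "H")),
    NOCount = sum(g$elem %in% c("N", "O")),
    NHOHCount = sum(g$nH[g$elem %in% c("N", "O")]),
    NumRotatableBonds = NA_real_)  # filled from SMARTS below
}

#' Compute descriptor vectors for a compound set
#'
#' Builds the named descriptor matrix over the configured allowlist plus
#' the two externally supplied property columns `logp` and `bpka1` (these
#' are predicted by an external tool and consumed as inputs; a crude
#' computed fallback is available as `logp_calc_fallback`, named so that a
#' model can never silently mix the two sources).
#'
#' @param smiles character vector of SMILES.
#' @param external data.frame with numeric columns `logp` and `bpka1`
#'   aligned with `smiles` (NA bpka1 allowed for compounds without a basic
#'   center; it is encoded as NA and must be imputed or filtered before
#'   modeling on window compounds, where it is always present).
#' @param allowlist descriptor names; validated against the available set.
#' @param ids row identifiers.
#' @param logp_calc_fallback if TRUE, add OpenBabel's computed log P under
#'   the separate name `logp_calc_fallback`.
#' @return numeric matrix (rows = compounds, columns = descriptors), with
#'   `logp` and `bpka1` as the final columns.
#' @export
compute_descriptors <- function(smiles, external,
                                allowlist = default_descriptor_allowlist(),
                                ids = NULL, logp_calc_fallback = FALSE) {
  allowlist <- .validate_allowlist(allowlist)
  stopifnot(all(c("logp", "bpka1") %in% names(external)),
            nrow(external) == length(smiles))
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  mols <- parse_smiles(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) stop("unparseable SMILES at position(s): ",
                     paste(head(which(bad)), collapse = ", "))
  n <- length(smiles)
  out <- matrix(NA_real_, n, length(allowlist),
                dimnames = list(ids, allowlist))
  graph_cols <- intersect(allowlist, .GRAPH_DESCRIPTORS)
  if (length(graph_cols) > 0) {
    gd <- t(vapply(mols, .graph_descriptors,
                   numeric(length(.GRAPH_DESCRIPTORS))))
    out[, graph_cols] <- gd[, graph_cols, drop = FALSE]
  }
  ob_cols <- intersect(allowlist, names(.OB_DESCRIPTORS))
  fr_cols <- intersect(allowlist, names(.FR_SMARTS))
  need_sdf <- length(ob_cols) > 0 || length(fr_cols) > 0 ||
    "NumRotatableBonds" %in% allowlist || logp_calc_fallback
  if (need_sdf) {
    multi <- vapply(mols, function(g) g$n > 1, logical(1))
    sdfset <- if (any(multi))
      .smiles_to_sdfset(vapply(mols[multi], `[[`, character(1), "smiles"),
                        ids[multi]) else NULL
    if (length(ob_cols) > 0 || logp_calc_fallback) {
      if (!is.null(sdfset)) {
        props <- ChemmineR::propOB(sdfset)
        for (col in ob_cols) {
          out[multi, col] <- props[[.OB_DESCRIPTORS[[col]]]]
        }
        if (logp_calc_fallback) {
          out <- cbind(out, logp_calc_fallback = NA_real_)
          out[multi, "logp_calc_fallback"] <- props$logP
        }
      }
      ## single heavy atoms: no polar surface or acceptors beyond element
      for (i in which(!multi)) {
        for (col in ob_cols) out[i, col] <- .single_atom_descriptor(
          mols[[i]], col)
      }
    }
    count_smarts <- function(smarts) {
      cnt <- numeric(n)
      if (!is.null(sdfset)) {
        cnt[multi] <- as.numeric(
          ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
      }
      cnt
    }
    for (col in fr_cols) out[, col] <- count_smarts(.FR_SMARTS[[col]])
    if ("NumRotatableBonds" %in% allowlist) {
      out[, "NumRotatableBonds"] <- count_smarts(.ROTATABLE_SMARTS)
    }
  }
  cbind(out, logp = external$logp, bpka1 = external$bpka1)
}

.single_atom_descriptor <- function(g, col) {
  switch(col,
         TPSA = if (g$elem %in% c("N", "O")) 20 else 0,
         NumHAcceptors = as.numeric(g$elem %in% c("N", "O")),
         NumHDonors = as.numeric(g$elem %in% c("N", "O") && g$nH > 0),
         MolMR = 0,
         0)
}
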