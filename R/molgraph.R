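## Internal molecular graph layer.
##
## SMILES parsing, canonicalization and SMARTS matching are delegated to
## OpenBabel through ChemmineR/ChemmineOB. On top of the parsed connection
## table this file maintains a light heavy-atom graph (elements, charges,
## implicit hydrogens, kekulized bond orders, ring membership) that the MMP
## fragmenter and the Morgan fingerprinter operate on directly.

.lyso_cache <- new.env(parent = emptyenv())

.STD_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Se = c(2L, 4L, 6L), Br = 1L, I = 1L, At = 1L
)

.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53, At = 85
)

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904, At = 210
)

## MDL V2000 atom-block charge codes -> formal charge
.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

#' Canonicalize a SMILES string
#'
#' Returns the OpenBabel canonical SMILES. Results are memoized for the
#' session because MMP fragmentation canonicalizes many repeated fragments.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    key <- paste0("smi:", s)
    hit <- .lyso_cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) NA_character_
    )
    out <- .clean_smiles_output(out)
    assign(key, out, envir = .lyso_cache)
    out
  }, character(1), USE.NAMES = FALSE)
}

.clean_smiles_output <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_character_)
  x <- sub("[\t\n\r ].*$", "", x)
  if (!nzchar(x)) NA_character_ else x
}

.canonical_molblock <- function(molblock) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", source = molblock),
    error = function(e) NA_character_
  )
  .clean_smiles_output(out)
}

## Recognize a SMILES encoding a single heavy atom (ChemmineR cannot
## round-trip those through SDF), e.g. "C", "[NH4+]", "[Cl-]".
.single_atom_smiles <- function(smiles) {
  m <- regmatches(
    smiles,
    regexec("^\\[?([A-Z][a-z]?)(?:H[0-9]*)?([+-][0-9]?)?\\]?$", smiles)
  )[[1]]
  if (length(m) == 0) return(NULL)
  elem <- m[2]
  if (!elem %in% names(.STD_VALENCE)) return(NULL)
  chg <- m[3]
  charge <- if (!nzchar(chg)) 0L else {
    n <- sub("[+-]", "", chg)
    mag <- if (nzchar(n)) as.integer(n) else 1L
    if (substr(chg, 1, 1) == "-") -mag else mag
  }
  list(elem = elem, charge = charge)
}

.implicit_h <- function(elem, charge, bondsum) {
  val <- .STD_VALENCE[[elem]]
  if (is.null(val)) return(0L)
  ## common charge adjustments for organic subset
  if (elem == "N" && charge == 1L) val <- 4L
  if (elem == "N" && charge == -1L) val <- 2L
  if (elem == "O" && charge == 1L) val <- 3L
  if (elem == "O" && charge == -1L) val <- 1L
  if (elem == "C" && charge != 0L) val <- 3L
  if (elem %in% c("F", "Cl", "Br", "I") && charge == -1L) val <- 0L
  v <- val[val >= bondsum]
  if (length(v) == 0) return(0L)
  as.integer(min(v) - bondsum)
}

.molgraph_finalize <- function(g) {
  n <- g$n
  nb <- if (is.null(g$bonds)) 0L else nrow(g$bonds)
  g$degree <- integer(n)
  bondsum <- integer(n)
  if (nb > 0) {
    for (k in seq_len(nb)) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      g$degree[i] <- g$degree[i] + 1L; g$degree[j] <- g$degree[j] + 1L
      bondsum[i] <- bondsum[i] + o; bondsum[j] <- bondsum[j] + o
    }
  }
  g$nH <- vapply(seq_len(n), function(i)
    .implicit_h(g$elem[i], g$charge[i], bondsum[i]), integer(1))
  ## ring perception: a bond is in a ring iff it is not a bridge
  if (nb > 0) {
    ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    br <- as.integer(igraph::bridges(ig))
    g$ring_bond <- !(seq_len(nb) %in% br)
    g$ring_atom <- rep(FALSE, n)
    for (k in which(g$ring_bond)) {
      g$ring_atom[g$bonds[k, 1]] <- TRUE
      g$ring_atom[g$bonds[k, 2]] <- TRUE
    }
  } else {
    g$ring_bond <- logical(0)
    g$ring_atom <- rep(FALSE, n)
  }
  class(g) <- "molgraph"
  g
}

.molgraph_from_sdf <- function(sdf, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  charge <- integer(n)
  if (ncol(ab) >= 5) {
    code <- as.character(as.integer(ab[, 5]))
    charge <- unname(.MDL_CHARGE[code])
    charge[is.na(charge)] <- 0L
  }
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0) {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                   as.integer(bb[, 3]))
  } else {
    bonds <- matrix(integer(0), ncol = 3)
  }
  .molgraph_finalize(list(n = n, elem = elem, charge = charge,
                          bonds = bonds, smiles = smiles))
}

#' Parse SMILES into internal molecular graphs
#'
#' @param smiles character vector of SMILES.
#' @return a list of `molgraph` objects (NULL where a structure failed to
#'   parse), named by canonical SMILES.
#' @export
parse_smiles <- function(smiles) {
  can <- canonical_smiles(smiles)
  out <- vector("list", length(smiles))
  multi <- which(!is.na(can) & vapply(can, function(s)
    is.null(.single_atom_smiles(s)), logical(1)))
  if (length(multi) > 0) {
    sdfset <- suppressWarnings(tryCatch(
      ChemmineR::smiles2sdf(setNames(can[multi], paste0("m", seq_along(multi)))),
      error = function(e) NULL))
    if (!is.null(sdfset)) {
      ok <- ChemmineR::validSDF(sdfset)
      for (k in seq_along(multi)) {
        if (k <= length(sdfset) && ok[k]) {
          out[[multi[k]]] <- .molgraph_from_sdf(sdfset[[k]], can[multi[k]])
        }
      }
    }
  }
  singles <- which(!is.na(can) & !vapply(can, function(s)
    is.null(.single_atom_smiles(s)), logical(1)))
  for (k in singles) {
    a <- .single_atom_smiles(can[k])
    out[[k]] <- .molgraph_finalize(list(
      n = 1L, elem = a$elem, charge = a$charge,
      bonds = matrix(integer(0), ncol = 3), smiles = can[k]))
  }
  names(out) <- can
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, " (", x$n, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Heavy atom count of a molecule
#'
#' @param x a `molgraph` or SMILES string.
#' @return integer heavy-atom count (`NA` if unparseable).
#' @export
heavy_atom_count <- function(x) {
  if (inherits(x, "molgraph")) return(x$n)
  vapply(parse_smiles(x), function(g) if (is.null(g)) NA_integer_ else g$n,
         integer(1), USE.NAMES = FALSE)
}

## molecular weight (average masses); heavy_only drops hydrogens
.mol_weight <- function(g, heavy_only = FALSE) {
  w <- sum(.ATOMIC_MASS[g$elem])
  if (!heavy_only) w <- w + sum(g$nH) * .ATOMIC_MASS[["H"]]
  unname(w)
}

## Write a minimal V2000 molblock for a (sub)graph. Charges go in an
## "M  CHG" property line; coordinates are zero (connectivity only).
.molgraph_to_molblock <- function(g) {
  nb <- nrow(g$bonds)
  header <- c("", "  lysoprofiler", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n, nb)
  atoms <- vapply(seq_len(g$n), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$elem[i]), character(1))
  bonds <- character(0)
  if (nb > 0) {
    bonds <- vapply(seq_len(nb), function(k)
      sprintf("%3d%3d%3d  0  0  0  0", g$bonds[k, 1], g$bonds[k, 2],
              g$bonds[k, 3]), character(1))
  }
  chg <- which(g$charge != 0L)
  extra <- character(0)
  if (length(chg) > 0) {
    extra <- paste0("M  CHG", sprintf("%3d", length(chg)),
                    paste0(sprintf("%4d%4d", chg, g$charge[chg]),
                           collapse = ""))
  }
  paste(c(header, counts, atoms, bonds, extra, "M  END", "$$$$"),
        collapse = "\n")
}

## Canonical SMILES of an induced subgraph, optionally with an attachment
## dummy atom (astatine, written [At]) bonded to `attach_to`.
.subgraph_smiles <- function(g, atoms, bonds_keep = NULL, attach_to = NULL) {
  atoms <- sort(unique(atoms))
  idx <- match(seq_len(g$n), atoms)     # old -> new
  nb <- nrow(g$bonds)
  keep <- if (is.null(bonds_keep)) {
    which(g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms)
  } else bonds_keep
  sub <- list(
    n = length(atoms),
    elem = g$elem[atoms],
    charge = g$charge[atoms],
    bonds = if (length(keep) > 0)
      cbind(idx[g$bonds[keep, 1]], idx[g$bonds[keep, 2]],
            g$bonds[keep, 3])
    else matrix(integer(0), ncol = 3)
  )
  if (!is.null(attach_to)) {
    for (a in attach_to) {
      sub$elem <- c(sub$elem, "At")
      sub$charge <- c(sub$charge, 0L)
      sub$n <- sub$n + 1L
      sub$bonds <- rbind(sub$bonds, c(idx[a], sub$n, 1L))
    }
  }
  sub <- .molgraph_finalize(sub)
  key <- paste0("mb:", paste(sub$elem, collapse = ""),
                paste(t(sub$bonds), collapse = ","),
                paste(sub$charge, collapse = ","))
  hit <- .lyso_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .canonical_molblock(.molgraph_to_molblock(sub))
  assign(key, out, envir = .lyso_cache)
  out
}

## Build an SDFset from a character vector of SMILES (multi-atom only),
## used to feed OpenBabel descriptor/SMARTS/fingerprint calculators.
.smiles_to_sdfset <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
  ChemmineR::cid(sdfset) <- ids
  sdfset
}
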