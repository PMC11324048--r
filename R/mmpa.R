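## Matched molecular pair analysis over the lyso score.
##
## Single-cut fragmentation of every acyclic single bond (plus
## hydrogen-replacement sites) yields constant/variable fragment pairs;
## fragmentations are indexed by their canonical constant to find compound
## pairs differing by one localized change, and transformation rules
## aggregate the lyso-score deltas of all pairs sharing a variable-A to
## variable-B change.

#' MMP fragmentation configuration
#'
#' @param max_variable_heavies maximum heavy atoms in the variable part.
#' @param include_hydrogen also emit hydrogen-replacement fragmentations
#'   (variable = H at each heavy atom bearing at least one hydrogen), so
#'   that additions (H to X) are found as MMPs.
#' @return named list.
#' @export
mmpa_config <- function(max_variable_heavies = 10L, include_hydrogen = TRUE) {
  list(max_variable_heavies = as.integer(max_variable_heavies),
       include_hydrogen = include_hydrogen)
}

## canonical fragment string for the hydrogen variable
.H_VARIABLE <- "[AtH]"

.adjacency <- function(g) {
  adj <- vector("list", g$n)
  nb <- nrow(g$bonds)
  if (nb > 0) {
    for (k in seq_len(nb)) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## atoms reachable from `start` when bond (a,b) is removed
.component_without_bond <- function(adj, start, a, b) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  queue <- start
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

#' Fragment a molecule into constant/variable pairs
#'
#' Enumerates every single cut of an acyclic single bond. For each cut the
#' side holding at least half of the parent's heavy atoms can serve as the
#' constant and the other side as the variable, subject to the variable
#' size cap. When `include_hydrogen` is set, each heavy atom carrying at
#' least one hydrogen additionally yields a fragmentation whose constant is
#' the whole molecule (attachment at that atom) and whose variable is a
#' hydrogen. Fragments are canonical SMILES carrying an astatine attachment
#' token (`[At]`), astatine never occurring in screening compounds.
#'
#' @param mol a `molgraph` (or a single SMILES string).
#' @param parent_id identifier recorded with each fragmentation.
#' @param cfg an [mmpa_config()].
#' @return data.frame: parent_id, constant, variable, n_heavy_variable,
#'   type ("cut" or "hydrogen"). Zero rows for molecules with no acyclic
#'   single bonds and no hydrogens.
#' @export
fragment_molecule <- function(mol, parent_id = "mol", cfg = mmpa_config()) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  if (is.null(mol)) stop("unparseable molecule")
  adj <- .adjacency(mol)
  rows <- list()
  nb <- nrow(mol$bonds)
  cut_bonds <- if (nb > 0) {
    which(mol$bonds[, 3] == 1L & !mol$ring_bond)
  } else integer(0)
  for (k in cut_bonds) {
    a <- mol$bonds[k, 1]; b <- mol$bonds[k, 2]
    side_a <- .component_without_bond(adj, a, a, b)
    side_b <- setdiff(seq_len(mol$n), side_a)
    for (orient in 1:2) {
      const_atoms <- if (orient == 1) side_a else side_b
      var_atoms <- if (orient == 1) side_b else side_a
      const_attach <- if (orient == 1) a else b
      var_attach <- if (orient == 1) b else a
      if (2 * length(const_atoms) < mol$n) next
      if (length(var_atoms) > cfg$max_variable_heavies) next
      rows[[length(rows) + 1]] <- data.frame(
        parent_id = parent_id,
        constant = .subgraph_smiles(mol, const_atoms,
                                    attach_to = const_attach),
        variable = .subgraph_smiles(mol, var_atoms, attach_to = var_attach),
        n_heavy_variable = length(var_atoms),
        type = "cut", stringsAsFactors = FALSE)
    }
  }
  if (cfg$include_hydrogen) {
    for (a in which(mol$nH >= 1L)) {
      rows[[length(rows) + 1]] <- data.frame(
        parent_id = parent_id,
        constant = .subgraph_smiles(mol, seq_len(mol$n), attach_to = a),
        variable = .H_VARIABLE,
        n_heavy_variable = 0L,
        type = "hydrogen", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(parent_id = character(0), constant = character(0),
                      variable = character(0), n_heavy_variable = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("constant", "variable")]), , drop = FALSE]
}

#' Fragment a compound library
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers (defaults to the SMILES).
#' @param cfg an [mmpa_config()].
#' @return data.frame of fragmentations over all parseable compounds.
#' @export
fragment_library <- function(smiles, ids = smiles, cfg = mmpa_config()) {
  mols <- parse_smiles(smiles)
  frags <- lapply(seq_along(mols), function(i) {
    if (is.null(mols[[i]])) return(NULL)
    fragment_molecule(mols[[i]], ids[i], cfg)
  })
  out <- do.call(rbind, frags)
  if (is.null(out)) {
    out <- data.frame(parent_id = character(0), constant = character(0),
                      variable = character(0), n_heavy_variable = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Index fragmentations into matched molecular pairs
#'
#' Groups fragmentations by canonical constant and emits one MMP for every
#' unordered compound pair that shares a constant with differing variables.
#' The pair direction is canonical: variables are ordered lexicographically
#' by their canonical fragment string, and the lyso-score delta is
#' `lyso(to) - lyso(from)` in that orientation, so each unordered pair
#' appears exactly once per shared constant.
#'
#' @param library data.frame with columns `compound_id`, `smiles` and
#'   `lyso_score`.
#' @param cfg an [mmpa_config()].
#' @param fragments optional precomputed [fragment_library()] output.
#' @return data.frame of MMPs: id_from, id_to, constant, variable_from,
#'   variable_to, lyso_from, lyso_to, delta_lyso.
#' @export
index_pairs <- function(library, cfg = mmpa_config(), fragments = NULL) {
  stopifnot(all(c("compound_id", "smiles", "lyso_score") %in% names(library)))
  if (is.null(fragments)) {
    fragments <- fragment_library(library$smiles, library$compound_id, cfg)
  }
  empty <- data.frame(
    id_from = character(0), id_to = character(0), constant = character(0),
    variable_from = character(0), variable_to = character(0),
    lyso_from = numeric(0), lyso_to = numeric(0), delta_lyso = numeric(0),
    stringsAsFactors = FALSE)
  if (nrow(fragments) == 0) return(empty)
  lyso <- setNames(library$lyso_score, library$compound_id)
  rows <- list()
  for (grp in split(fragments, fragments$constant)) {
    if (length(unique(grp$parent_id)) < 2) next
    ids <- unique(grp$parent_id)
    for (ii in seq_len(length(ids) - 1)) {
      for (jj in seq(ii + 1, length(ids))) {
        vi <- grp$variable[grp$parent_id == ids[ii]]
        vj <- grp$variable[grp$parent_id == ids[jj]]
        ## all distinct variable combinations on this shared constant
        combos <- unique(expand.grid(a = vi, b = vj,
                                     stringsAsFactors = FALSE))
        combos <- combos[combos$a != combos$b, , drop = FALSE]
        if (nrow(combos) == 0) next
        ## one MMP per unordered pair per constant: take the
        ## lexicographically smallest (from, to) variable combination
        key <- ifelse(combos$a <= combos$b,
                      paste(combos$a, combos$b, sep = ">>"),
                      paste(combos$b, combos$a, sep = ">>"))
        pick <- which(key == min(key))[1]
        a <- combos$a[pick]; b <- combos$b[pick]
        if (a <= b) {
          from_id <- ids[ii]; to_id <- ids[jj]
          vf <- a; vt <- b
        } else {
          from_id <- ids[jj]; to_id <- ids[ii]
          vf <- b; vt <- a
        }
        rows[[length(rows) + 1]] <- data.frame(
          id_from = from_id, id_to = to_id,
          constant = grp$constant[1],
          variable_from = vf, variable_to = vt,
          lyso_from = unname(lyso[from_id]), lyso_to = unname(lyso[to_id]),
          delta_lyso = unname(lyso[to_id] - lyso[from_id]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive transformation rules from MMPs
#'
#' Groups MMPs by their (variable_from, variable_to) transformation,
#' irrespective of the context the change occurred in, and aggregates the
#' lyso-score deltas: frequency of occurrence, the delta distribution and
#' its median. Rules are sorted by count, descending.
#'
#' @param mmps data.frame from [index_pairs()].
#' @return data.frame: variable_from, variable_to, smirks, count,
#'   median_delta, plus a list-column `deltas`.
#' @export
derive_rules <- function(mmps) {
  if (nrow(mmps) == 0) stop("no MMPs to aggregate")
  key <- paste(mmps$variable_from, mmps$variable_to, sep = ">>")
  groups <- split(mmps$delta_lyso, key)
  out <- data.frame(
    variable_from = vapply(strsplit(names(groups), ">>", fixed = TRUE),
                           `[`, character(1), 1),
    variable_to = vapply(strsplit(names(groups), ">>", fixed = TRUE),
                         `[`, character(1), 2),
    smirks = names(groups),
    count = vapply(groups, length, integer(1)),
    median_delta = vapply(groups, median, numeric(1)),
    stringsAsFactors = FALSE)
  out$deltas <- unname(groups)
  out <- out[order(-out$count, out$variable_from, out$variable_to), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the lysosomotropism transition of an MMP
#'
#' A pair is a class switch when exactly one endpoint reaches the lyso
#' threshold (the threshold itself counts as lysosomotropic).
#'
#' @param lyso_from,lyso_to lyso scores of the two endpoints.
#' @param threshold lyso-score threshold.
#' @return character vector with values `nonlyso_to_nonlyso`,
#'   `lyso_to_lyso`, `class_switch`.
#' @export
classify_transition <- function(lyso_from, lyso_to, threshold = 75) {
  a <- lyso_from >= threshold
  b <- lyso_to >= threshold
  ifelse(xor(a, b), "class_switch",
         ifelse(a & b, "lyso_to_lyso", "nonlyso_to_nonlyso"))
}

#' Write MMPs and rules to CSV
#'
#' The rules' delta distributions are serialized as semicolon-joined
#' strings for interchange.
#'
#' @param mmps data.frame from [index_pairs()].
#' @param rules data.frame from [derive_rules()].
#' @param mmp_path,rules_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_mmpa_csv <- function(mmps, rules, mmp_path, rules_path) {
  write.csv(mmps, mmp_path, row.names = FALSE)
  flat <- rules
  flat$deltas <- vapply(rules$deltas, function(d)
    paste(format(d, trim = TRUE), collapse = ";"), character(1))
  write.csv(flat, rules_path, row.names = FALSE)
  invisible(list(mmps = mmp_path, rules = rules_path))
}
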