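## Binary molecular fingerprints.
##
## Circular (Morgan-style) fingerprints are computed natively on the
## internal molecular graph so that every on-bit can be traced back to the
## (atom, radius) environments that set it -- the provenance needed to turn
## "bit 2715 is important" into "this substructure is important". The
## hashing is deterministic but makes no claim of bit-compatibility with
## any other toolkit. MACCS-type structural keys (166 predefined features)
## are delegated to OpenBabel.

#' Fingerprint specification
#'
#' @param kind `"circular"` or `"structural_keys"`.
#' @param radius maximum environment radius (circular only); the radii
#'   used in practice are 2, 3 and 4.
#' @param n_bits folded length, a power of two. 4096 is the default: a
#'   4096-bit space keeps hash collisions rare at screening-library scale
#'   while indices stay in the familiar 0..4095 range.
#' @param track_bits record bit-to-substructure provenance.
#' @return named list.
#' @export
fingerprint_spec <- function(kind = c("circular", "structural_keys"),
                             radius = 2L, n_bits = 4096L,
                             track_bits = TRUE) {
  kind <- match.arg(kind)
  n_bits <- as.integer(n_bits)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L || n_bits <= 0L) {
    stop("n_bits must be a power of two")
  }
  stopifnot(radius >= 0)
  list(kind = kind, radius = as.integer(radius), n_bits = n_bits,
       track_bits = track_bits)
}

## deterministic polynomial hash of an integer stream, mod 2^31-1
.HASH_MOD <- 2147483647
.hash_ints <- function(ints) {
  h <- 17
  for (v in ints) h <- (h * 31 + (v %% .HASH_MOD)) %% .HASH_MOD
  h
}

## initial atom invariants: atomic number, heavy degree, implicit H count,
## formal charge, ring membership
.atom_invariants <- function(g) {
  z <- unname(.ATOMIC_NUMBER[g$elem])
  vapply(seq_len(g$n), function(i)
    .hash_ints(c(z[i], g$degree[i], g$nH[i], g$charge[i] + 10L,
                 as.integer(g$ring_atom[i]))), numeric(1))
}

#' Circular fingerprint with bit provenance
#'
#' Iteratively hashes each atom's neighborhood out to the requested radius
#' (environments of all radii 0..radius contribute) and folds the
#' environment identifiers into an `n_bits` binary vector. With
#' `track_bits`, every on-bit records the (atom, radius) environments that
#' set it; re-hashing any recorded environment reproduces its bit.
#'
#' @param mol a `molgraph` or single SMILES string.
#' @param spec a [fingerprint_spec()] of kind `"circular"`.
#' @return object of class `fingerprint`: list with `bits` (integer 0/1
#'   vector), `on_bits` (0-based indices), and `bit_info` (named list:
#'   bit index -> matrix with columns atom, radius).
#' @export
circular_fingerprint <- function(mol, spec = fingerprint_spec()) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  if (is.null(mol)) stop("unparseable molecule")
  stopifnot(spec$kind == "circular")
  inv <- .atom_invariants(mol)
  adj <- .adjacency(mol)
  ## bond order lookup for neighbor pairs
  order_of <- new.env(parent = emptyenv())
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]; o <- mol$bonds[k, 3]
      assign(paste(i, j), o, envir = order_of)
      assign(paste(j, i), o, envir = order_of)
    }
  }
  envs <- list()  # list of (atom, radius, id)
  for (a in seq_len(mol$n)) {
    envs[[length(envs) + 1]] <- c(a, 0L, inv[a])
  }
  cur <- inv
  if (spec$radius > 0) {
    for (r in seq_len(spec$radius)) {
      nxt <- numeric(mol$n)
      for (a in seq_len(mol$n)) {
        nbrs <- adj[[a]]
        if (length(nbrs) == 0) {
          ## isolated atom: the environment stopped growing at radius 0,
          ## so no higher-radius environments are recorded
          nxt[a] <- cur[a]
          next
        }
        pairs <- cbind(
          vapply(nbrs, function(b) get(paste(a, b), envir = order_of),
                 numeric(1)),
          cur[nbrs])
        ord <- order(pairs[, 1], pairs[, 2])
        stream <- c(r, cur[a], as.vector(t(pairs[ord, , drop = FALSE])))
        nxt[a] <- .hash_ints(stream)
        envs[[length(envs) + 1]] <- c(a, r, nxt[a])
      }
      cur <- nxt
    }
  }
  bits <- integer(spec$n_bits)
  bit_info <- list()
  for (e in envs) {
    bit <- e[3] %% spec$n_bits
    bits[bit + 1L] <- 1L
    if (spec$track_bits) {
      key <- as.character(bit)
      bit_info[[key]] <- rbind(bit_info[[key]],
                               c(atom = e[1], radius = e[2]))
    }
  }
  structure(list(bits = bits, on_bits = which(bits == 1L) - 1L,
                 bit_info = if (spec$track_bits) bit_info else NULL,
                 spec = spec, mol = mol),
            class = "fingerprint")
}

#' Recompute the bit index of a recorded environment
#'
#' Provenance round-trip: re-hashes the (atom, radius) environment of a
#' molecule and folds it, reproducing the bit index it set.
#'
#' @param mol a `molgraph`.
#' @param atom atom index.
#' @param radius environment radius.
#' @param spec a [fingerprint_spec()].
#' @return 0-based bit index.
#' @export
environment_bit <- function(mol, atom, radius, spec = fingerprint_spec()) {
  fp <- circular_fingerprint(mol, fingerprint_spec(
    "circular", radius = max(radius, spec$radius), n_bits = spec$n_bits,
    track_bits = TRUE))
  for (key in names(fp$bit_info)) {
    m <- fp$bit_info[[key]]
    if (any(m[, "atom"] == atom & m[, "radius"] == radius)) {
      return(as.integer(key))
    }
  }
  stop("environment not found")
}

#' Decode the substructure of an atom environment
#'
#' Extracts the subgraph spanned by all atoms within `radius` bonds of the
#' center (bonds between two frontier atoms excluded) and returns its
#' canonical SMILES. Radius-0 environments decode to the bare atom.
#'
#' @param mol a `molgraph`.
#' @param atom center atom index.
#' @param radius environment radius.
#' @return canonical SMILES of the environment substructure.
#' @export
decode_environment <- function(mol, atom, radius) {
  if (radius == 0 || mol$n == 1) {
    g1 <- .molgraph_finalize(list(n = 1L, elem = mol$elem[atom],
                                  charge = mol$charge[atom],
                                  bonds = matrix(integer(0), ncol = 3)))
    return(.canonical_molblock(.molgraph_to_molblock(g1)))
  }
  adj <- .adjacency(mol)
  dist <- rep(Inf, mol$n)
  dist[atom] <- 0
  queue <- atom
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    if (dist[v] >= radius) next
    for (w in adj[[v]]) {
      if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
  }
  atoms <- which(dist <= radius)
  keep <- which(
    mol$bonds[, 1] %in% atoms & mol$bonds[, 2] %in% atoms &
      (dist[mol$bonds[, 1]] < radius | dist[mol$bonds[, 2]] < radius))
  .subgraph_smiles(mol, atoms, bonds_keep = keep)
}

#' MACCS-type structural keys
#'
#' The 166 predefined structural keys, computed by OpenBabel and truncated
#' from its padded 256-bit vector to the 166 defined keys.
#'
#' @param smiles character vector of SMILES.
#' @param ids row names.
#' @return integer matrix (rows = compounds, 166 columns `key_1`..`key_166`).
#' @export
structural_keys <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  mols <- parse_smiles(smiles)
  multi <- vapply(mols, function(g) !is.null(g) && g$n > 1, logical(1))
  out <- matrix(0L, length(smiles), 166,
                dimnames = list(ids, paste0("key_", 1:166)))
  if (any(multi)) {
    sdfset <- .smiles_to_sdfset(
      vapply(mols[multi], `[[`, character(1), "smiles"), ids[multi])
    fpset <- ChemmineR::fingerprintOB(sdfset, "MACCS")
    m <- methods::slot(fpset, "fpma")   # 256-bit padded key matrix
    out[multi, ] <- as.integer(m[, 1:166])
  }
  out
}

#' Fingerprint matrix for a compound set
#'
#' @param smiles character vector of SMILES.
#' @param spec a [fingerprint_spec()].
#' @param ids row names.
#' @return for circular specs, a list with `X` (integer matrix, columns
#'   `bit_0`..`bit_<n-1>`), `fingerprints` (per-compound [circular_fingerprint()]
#'   objects carrying bit provenance) and `spec`; for structural keys, the
#'   same shape with the 166-column key matrix.
#' @export
fingerprint_matrix <- function(smiles, spec = fingerprint_spec(),
                               ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  if (spec$kind == "structural_keys") {
    return(list(X = structural_keys(smiles, ids), fingerprints = NULL,
                spec = spec))
  }
  mols <- parse_smiles(smiles)
  fps <- lapply(mols, function(g) {
    if (is.null(g)) stop("unparseable SMILES in fingerprint_matrix")
    circular_fingerprint(g, spec)
  })
  X <- do.call(rbind, lapply(fps, `[[`, "bits"))
  dimnames(X) <- list(ids, paste0("bit_", seq_len(spec$n_bits) - 1L))
  names(fps) <- ids
  list(X = X, fingerprints = fps, spec = spec)
}

#' Tanimoto similarity of two fingerprints
#'
#' @param a,b `fingerprint` objects or 0/1 vectors.
#' @return |intersection| / |union| of on-bit sets (1 if both empty).
#' @export
tanimoto <- function(a, b) {
  oa <- if (inherits(a, "fingerprint")) a$on_bits else which(a != 0)
  ob <- if (inherits(b, "fingerprint")) b$on_bits else which(b != 0)
  u <- length(union(oa, ob))
  if (u == 0) return(1)
  length(intersect(oa, ob)) / u
}
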