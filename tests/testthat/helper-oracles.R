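## Independent oracles and fixture builders shared across test files.

## Reassemble an MMP fragmentation: join the constant and variable
## fragments at their [At] attachment atoms (an H variable simply strips
## the attachment from the constant). Uses only the low-level graph
## editing + canonicalization primitives, not the fragmenter.
join_fragments <- function(constant, variable) {
  strip <- function(g) {
    at <- which(g$elem == "At")
    stopifnot(length(at) == 1)
    nbr <- NULL
    if (nrow(g$bonds) > 0) {
      k <- which(g$bonds[, 1] == at | g$bonds[, 2] == at)
      stopifnot(length(k) <= 1)
      if (length(k) == 1) {
        nbr <- setdiff(g$bonds[k, 1:2], at)
        g$bonds <- g$bonds[-k, , drop = FALSE]
      }
    }
    keep <- setdiff(seq_len(g$n), at)
    idx <- match(seq_len(g$n), keep)
    g$elem <- g$elem[keep]
    g$charge <- g$charge[keep]
    g$n <- g$n - 1L
    if (nrow(g$bonds) > 0) {
      g$bonds <- cbind(idx[g$bonds[, 1]], idx[g$bonds[, 2]], g$bonds[, 3])
    }
    list(g = g, attach = if (is.null(nbr)) NULL else idx[nbr])
  }
  gc <- parse_smiles(constant)[[1]]
  sc <- strip(gc)
  if (variable == "[AtH]") {
    merged <- sc$g
  } else {
    gv <- parse_smiles(variable)[[1]]
    sv <- strip(gv)
    merged <- sc$g
    off <- merged$n
    merged$elem <- c(merged$elem, sv$g$elem)
    merged$charge <- c(merged$charge, sv$g$charge)
    merged$n <- merged$n + sv$g$n
    vb <- sv$g$bonds
    if (nrow(vb) > 0) vb <- cbind(vb[, 1] + off, vb[, 2] + off, vb[, 3])
    merged$bonds <- rbind(merged$bonds, vb,
                          c(sc$attach, sv$attach + off, 1L))
  }
  merged <- lysoprofiler:::.molgraph_finalize(merged)
  lysoprofiler:::.canonical_molblock(
    lysoprofiler:::.molgraph_to_molblock(merged))
}

## Brute-force MMP search: test every compound pair for shared constants
## with differing variables, one MMP per (pair, constant). Independent of
## the indexing implementation (which groups by constant first).
brute_force_mmps <- function(library, cfg = mmpa_config()) {
  frags <- lapply(seq_len(nrow(library)), function(i)
    fragment_molecule(library$smiles[i], library$compound_id[i], cfg))
  out <- list()
  n <- nrow(library)
  if (n < 2) return(data.frame())
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      fi <- frags[[i]]; fj <- frags[[j]]
      shared <- intersect(fi$constant, fj$constant)
      for (cst in shared) {
        vi <- fi$variable[fi$constant == cst]
        vj <- fj$variable[fj$constant == cst]
        combos <- expand.grid(a = vi, b = vj, stringsAsFactors = FALSE)
        combos <- combos[combos$a != combos$b, , drop = FALSE]
        if (nrow(combos) == 0) next
        key <- ifelse(combos$a <= combos$b,
                      paste(combos$a, combos$b, sep = ">>"),
                      paste(combos$b, combos$a, sep = ">>"))
        pick <- which(key == min(key))[1]
        a <- combos$a[pick]; b <- combos$b[pick]
        if (a <= b) {
          from <- library$compound_id[i]; to <- library$compound_id[j]
          vf <- a; vt <- b
        } else {
          from <- library$compound_id[j]; to <- library$compound_id[i]
          vf <- b; vt <- a
        }
        out[[length(out) + 1]] <- data.frame(
          id_from = from, id_to = to, constant = cst, variable_from = vf,
          variable_to = vt, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

## canonical sort order for MMP tables so implementations can be compared
sort_mmps <- function(df) {
  df <- df[order(df$id_from, df$id_to, df$constant, df$variable_from,
                 df$variable_to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Brute-force Shapley values by subset enumeration for a hand-built tree
## list (same flat format the C++ kernel consumes). The value function
## v(S) follows the cover-weighted path-dependent expectation: at a split
## on a feature in S follow x, otherwise average both branches by cover.
## single-precision round trip: boosters store features and thresholds in
## float32, so split comparisons must happen in that precision
fl32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4),
                            "numeric", size = 4, n = length(x))

brute_force_shapley <- function(trees, x) {
  p <- length(x)
  v_tree <- function(tr, node, S) {
    f <- tr$feature[node + 1]
    if (f < 0) return(tr$value[node + 1])
    l <- tr$left[node + 1]; r <- tr$right[node + 1]
    if ((f + 1) %in% S) {
      nxt <- if (fl32(x[f + 1]) < fl32(tr$threshold[node + 1])) l else r
      return(v_tree(tr, nxt, S))
    }
    cl <- tr$cover[l + 1]; cr <- tr$cover[r + 1]
    (cl * v_tree(tr, l, S) + cr * v_tree(tr, r, S)) / (cl + cr)
  }
  v <- function(S) sum(vapply(trees, v_tree, numeric(1), node = 0, S = S))
  phi <- numeric(p)
  others <- function(i) setdiff(seq_len(p), i)
  for (i in seq_len(p)) {
    rest <- others(i)
    for (k in 0:length(rest)) {
      subsets <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(rest, k), 2)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) {
        phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
      }
    }
  }
  phi
}

## flat hand-built tree helpers (0-based children/features, -1 = leaf)
leaf_tree <- function(value, cover = 1) {
  list(feature = -1L, left = -1L, right = -1L, threshold = 0,
       value = value, cover = cover)
}

stump_tree <- function(feature0, threshold, left_value, right_value,
                       left_cover, right_cover) {
  list(feature = c(feature0, -1L, -1L), left = c(1L, -1L, -1L),
       right = c(2L, -1L, -1L), threshold = c(threshold, 0, 0),
       value = c(0, left_value, right_value),
       cover = c(left_cover + right_cover, left_cover, right_cover))
}

## tiny deterministic separable dataset for model tests
separable_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(2 * n), x2 = rnorm(2 * n))
  keep <- which(abs(X[, "x1"] + X[, "x2"]) > 0.8)[seq_len(n)]  # wide margin
  X <- X[keep, , drop = FALSE]
  y <- as.integer(X[, "x1"] + X[, "x2"] > 0)
  list(X = X, y = y)
}
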