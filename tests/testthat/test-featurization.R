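ext <- function(n) data.frame(logp = rep(2.5, n), bpka1 = rep(8, n))

test_that("descriptor values match hand-derived expectations", {
  X <- compute_descriptors(c("c1ccccc1", "CC", "CCNCC"), ext(3),
                           ids = c("benzene", "ethane", "dea"))
  expect_equal(X["benzene", "TPSA"], 0)
  expect_equal(X["benzene", "FractionCSP3"], 0)
  expect_equal(X["ethane", "FractionCSP3"], 1)
  ## diethylamine: one secondary amine, nothing else N-ish
  expect_equal(X["dea", "fr_NH1"], 1)
  expect_equal(X["dea", "fr_NH2"], 0)
  expect_equal(X["dea", "fr_NH0"], 0)
  ## external columns pass through unchanged as the last two columns
  expect_identical(tail(colnames(X), 2), c("logp", "bpka1"))
  expect_equal(unname(X[, "logp"]), rep(2.5, 3))
  ## counts are non-negative integers
  frs <- grep("^fr_", colnames(X), value = TRUE)
  expect_true(all(X[, frs] >= 0))
  expect_true(all(X[, frs] == round(X[, frs])))
})

test_that("graph descriptors agree with formula-level oracles", {
  X <- compute_descriptors(c("c1ccccc1", "C1CC1C"), ext(2),
                           ids = c("benzene", "mcp"))
  expect_equal(X["benzene", "HeavyAtomCount"], 6)
  expect_equal(X["benzene", "RingCount"], 1)
  expect_equal(X["benzene", "HeavyAtomMolWt"], 6 * 12.011, tolerance = 1e-6)
  expect_equal(X["benzene", "MolWt"], 6 * 12.011 + 6 * 1.008,
               tolerance = 1e-6)
  expect_equal(X["benzene", "NumRotatableBonds"], 0)
  expect_equal(X["mcp", "FractionCSP3"], 1)
  expect_equal(X["mcp", "RingCount"], 1)
})

test_that("the allowlist rejects surface-partition and unknown descriptors", {
  expect_error(compute_descriptors("CC", ext(1), allowlist = c("TPSA", "PEOE_VSA7")),
               "surface-partition")
  expect_error(compute_descriptors("CC", ext(1), allowlist = c("TPSA", "SMR_VSA6")),
               "surface-partition")
  expect_error(compute_descriptors("CC", ext(1), allowlist = c("TPSA", "NotADescriptor")),
               "unknown")
  ## mandatory members of the default list
  expect_true(all(c("TPSA", "FractionCSP3", "NumHAcceptors", "fr_NH1",
                    "fr_nitro", "HeavyAtomMolWt") %in%
                  default_descriptor_allowlist()))
})

test_that("the computed log P fallback is separately named", {
  X <- compute_descriptors("CCO", ext(1), logp_calc_fallback = TRUE)
  expect_true("logp_calc_fallback" %in% colnames(X))
  expect_false(identical(X[, "logp_calc_fallback"], X[, "logp"]))
})

test_that("circular fingerprints are deterministic and order invariant", {
  spec <- fingerprint_spec("circular", radius = 2)
  a <- circular_fingerprint("CCN(CC)CCOc1ccc(Cl)cc1", spec)
  b <- circular_fingerprint("CCN(CC)CCOc1ccc(Cl)cc1", spec)
  expect_identical(a$bits, b$bits)
  ## same molecule written from a different atom ordering
  c_ <- circular_fingerprint("Clc1ccc(OCCN(CC)CC)cc1", spec)
  expect_identical(a$bits, c_$bits)
})

test_that("single-atom molecules carry only radius-0 environments", {
  fp <- circular_fingerprint("C", fingerprint_spec("circular", radius = 2))
  expect_identical(length(fp$on_bits), 1L)
  info <- do.call(rbind, fp$bit_info)
  expect_true(all(info[, "radius"] == 0))
})

test_that("ethanol's on-bits equal its distinct environment count", {
  ## ethanol has 3 heavy atoms; every (atom, radius) environment for radii
  ## 0..2 is structurally distinct (different center or different
  ## neighborhood), giving 9 distinct environments and, absent folding
  ## collisions at 4096 bits, 9 on-bits
  fp <- circular_fingerprint("CCO", fingerprint_spec("circular", radius = 2))
  expect_identical(length(fp$on_bits), 9L)
  n_envs <- sum(vapply(fp$bit_info, nrow, integer(1)))
  expect_identical(n_envs, 9L)
})

test_that("bit provenance round-trips through re-hashing", {
  spec <- fingerprint_spec("circular", radius = 2)
  mol <- parse_smiles("CCN(CC)CCOc1ccccc1")[[1]]
  fp <- circular_fingerprint(mol, spec)
  for (key in names(fp$bit_info)) {
    m <- fp$bit_info[[key]]
    for (r in seq_len(nrow(m))) {
      expect_identical(environment_bit(mol, m[r, "atom"], m[r, "radius"],
                                       spec),
                       as.integer(key))
    }
  }
  ## every on-bit has at least one recorded origin
  expect_setequal(as.integer(names(fp$bit_info)), fp$on_bits)
})

test_that("higher-radius on-bits are a superset of lower-radius bits", {
  for (s in c("CCN(CC)CCOc1ccc(Cl)cc1", "CN1CCN(CC1)c1ccccc1")) {
    mol <- parse_smiles(s)[[1]]
    bits <- lapply(2:4, function(r)
      circular_fingerprint(mol, fingerprint_spec("circular", radius = r))$on_bits)
    expect_true(all(bits[[1]] %in% bits[[2]]))
    expect_true(all(bits[[2]] %in% bits[[3]]))
  }
})

test_that("environment decoding yields the expected substructures", {
  mol <- parse_smiles("Cc1ccccc1")[[1]]
  methyl <- which(vapply(seq_len(mol$n), function(i)
    mol$elem[i] == "C" && mol$nH[i] == 3, logical(1)))
  expect_identical(decode_environment(mol, methyl, 0), "C")
  ## radius 1 around the methyl: methyl + ipso carbon
  expect_identical(decode_environment(mol, methyl, 1), "CC")
})

test_that("structural keys have length 166 and sensible ring behaviour", {
  K <- structural_keys(c("c1ccccc1", "C"), c("benzene", "methane"))
  expect_identical(dim(K), c(2L, 166L))
  ## benzene sets the aromaticity key of the public definitions
  expect_identical(K["benzene", "key_162"], 1L)
  ## methane sets no keys at all (single atom, no encoded features)
  expect_true(sum(K["methane", ]) == 0)
})

test_that("fingerprint specs validate their invariants", {
  expect_error(fingerprint_spec(n_bits = 1000), "power of two")
  expect_error(fingerprint_spec(radius = -1))
  fm <- fingerprint_matrix(c("CCO", "CCN"), fingerprint_spec("circular", 2,
                                                             n_bits = 512))
  expect_identical(dim(fm$X), c(2L, 512L))
  expect_identical(colnames(fm$X)[1], "bit_0")
})

test_that("tanimoto matches set arithmetic on known on-bit sets", {
  spec <- fingerprint_spec("circular", radius = 2)
  tol <- circular_fingerprint("Cc1ccccc1", spec)
  bz <- circular_fingerprint("c1ccccc1", spec)
  want <- length(intersect(tol$on_bits, bz$on_bits)) /
    length(union(tol$on_bits, bz$on_bits))
  expect_equal(tanimoto(tol, bz), want)
  expect_equal(tanimoto(tol, tol), 1)
  ## disjoint on-bit sets
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
})
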