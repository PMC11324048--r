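test_that("toluene fragmentation enumerates exactly its acyclic single bonds", {
  mol <- parse_smiles("Cc1ccccc1")[[1]]
  fr <- fragment_molecule(mol, "tol")
  cuts <- fr[fr$type == "cut", ]
  ## toluene has exactly one acyclic single bond (methyl-ring); only the
  ## ring side can be the constant (>= half the heavy atoms)
  expect_identical(nrow(cuts), 1L)
  expect_identical(cuts$variable, canonical_smiles("[At]C"))
  expect_identical(cuts$constant, canonical_smiles("[At]c1ccccc1"))
  expect_identical(cuts$n_heavy_variable, 1L)
  ## hydrogen replacements: methyl + ortho/meta/para (symmetry-deduped)
  expect_identical(nrow(fr[fr$type == "hydrogen", ]), 4L)
})

test_that("ring bonds are never cut; benzene and methane edge cases", {
  bz <- fragment_molecule("c1ccccc1", "bz")
  expect_true(all(bz$type == "hydrogen"))
  expect_identical(nrow(bz), 1L)   # all positions equivalent
  me <- fragment_molecule("C", "me")
  expect_identical(nrow(me), 1L)
  expect_identical(me$type, "hydrogen")
  expect_identical(me$variable, "[AtH]")
  ## no acyclic single bonds and no hydrogens: nothing to fragment
  none <- fragment_molecule("O=C=O", "co2", mmpa_config(include_hydrogen = FALSE))
  expect_identical(nrow(none), 0L)
})

test_that("reassembling constant and variable reproduces the parent", {
  smiles <- c("CCN(CC)CCOc1ccc(Cl)cc1", "Cc1ccccc1", "CN1CCN(CC1)c1ccccc1",
              "CC(C)Oc1ccccc1O")
  for (s in smiles) {
    parent <- canonical_smiles(s)
    fr <- fragment_molecule(s, "p")
    for (k in seq_len(nrow(fr))) {
      expect_identical(join_fragments(fr$constant[k], fr$variable[k]),
                       parent)
    }
  }
})

test_that("variable size cap and constant majority constraints hold", {
  cfg <- mmpa_config(max_variable_heavies = 3)
  fr <- fragment_molecule("CCCCCCCCCCc1ccccc1", "dec", cfg)
  cuts <- fr[fr$type == "cut", ]
  expect_true(all(cuts$n_heavy_variable <= 3))
  ## every constant holds at least half of the 16 heavy atoms
  n_const <- vapply(cuts$constant, function(s)
    heavy_atom_count(s) - 1L, integer(1))  # minus the [At] token
  expect_true(all(n_const >= 8))
})

test_that("a three-analog series yields exactly its three pairs", {
  lib <- data.frame(compound_id = c("tol", "clbz", "phoh"),
                    smiles = c("Cc1ccccc1", "Clc1ccccc1", "Oc1ccccc1"),
                    lyso_score = c(80, 30, 55),
                    stringsAsFactors = FALSE)
  mmps <- index_pairs(lib)
  ## Me<->Cl, Me<->OH, Cl<->OH on the shared phenyl constant
  phenyl <- mmps[mmps$constant == canonical_smiles("[At]c1ccccc1"), ]
  expect_identical(nrow(phenyl), 3L)
  ## delta follows the canonical (lexicographic) direction
  for (k in seq_len(nrow(phenyl))) {
    expect_true(phenyl$variable_from[k] <= phenyl$variable_to[k])
    expect_equal(phenyl$delta_lyso[k],
                 phenyl$lyso_to[k] - phenyl$lyso_from[k])
  }
})

test_that("degenerate libraries produce no pairs", {
  one <- data.frame(compound_id = "a", smiles = "Cc1ccccc1",
                    lyso_score = 50, stringsAsFactors = FALSE)
  expect_identical(nrow(index_pairs(one)), 0L)
  twins <- data.frame(compound_id = c("a", "b"),
                      smiles = c("Cc1ccccc1", "CC1=CC=CC=C1"),
                      lyso_score = c(50, 60), stringsAsFactors = FALSE)
  expect_identical(nrow(index_pairs(twins)), 0L)
})

test_that("indexing equals brute-force pair search on random libraries", {
  cfg <- generator_config(n_compounds = 60, seed = 99)
  lib <- generate_library(cfg)
  set.seed(100)
  for (rep in 1:6) {
    idx <- sample(nrow(lib), 10)
    sub <- data.frame(compound_id = lib$compound_id[idx],
                      smiles = lib$smiles[idx],
                      lyso_score = round(runif(10, 0, 100), 1),
                      stringsAsFactors = FALSE)
    got <- index_pairs(sub)
    want <- brute_force_mmps(sub)
    cols <- c("id_from", "id_to", "constant", "variable_from",
              "variable_to")
    if (nrow(want) == 0) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(sort_mmps(got[, cols]), sort_mmps(want[, cols]))
    }
  }
})

test_that("a scaffold with k substituents yields choose(k,2) pairs on it", {
  subs <- c("", "C", "Cl", "OC", "N(C)C", "C#N")
  k <- length(subs)
  smiles <- vapply(subs, function(r)
    lysoprofiler:::.instantiate_template(
      "CN1CCN(CC1)c1cc({R2})cc({R1})c1", r, ""), character(1))
  lib <- data.frame(compound_id = paste0("s", seq_len(k)), smiles = smiles,
                    lyso_score = seq(10, 90, length.out = k),
                    stringsAsFactors = FALSE)
  mmps <- index_pairs(lib)
  ## the scaffold constant: the scaffold with the attachment token at R1
  scaffold_constant <- canonical_smiles(lysoprofiler:::.instantiate_template(
    "CN1CCN(CC1)c1cc({R2})cc({R1})c1", "[At]", ""))
  on_scaffold <- mmps[mmps$constant == scaffold_constant, ]
  expect_identical(nrow(on_scaffold), as.integer(choose(k, 2)))
})

test_that("transformation rules aggregate deltas with correct medians", {
  mmps <- data.frame(
    id_from = c("a", "c", "e", "g"), id_to = c("b", "d", "f", "h"),
    constant = "[At]c1ccccc1",
    variable_from = c("X", "X", "X", "Y"),
    variable_to = c("Z", "Z", "Z", "Z"),
    lyso_from = c(80, 50, 20, 10), lyso_to = c(70, 50, 50, 40),
    delta_lyso = c(-10, 0, 30, 30), stringsAsFactors = FALSE)
  rules <- derive_rules(mmps)
  expect_identical(rules$count, c(3L, 1L))       # sorted descending
  expect_identical(rules$smirks[1], "X>>Z")
  expect_identical(rules$median_delta[1], 0)     # median of {-10, 0, 30}
  expect_identical(rules$deltas[[1]], c(-10, 0, 30))
  ## reversing every pair's direction negates each rule's median
  rev <- mmps
  rev$variable_from <- mmps$variable_to
  rev$variable_to <- mmps$variable_from
  rev$delta_lyso <- -mmps$delta_lyso
  rules_rev <- derive_rules(rev)
  expect_equal(rules_rev$median_delta[rules_rev$smirks == "Z>>X"],
               -rules$median_delta[rules$smirks == "X>>Z"])
})

test_that("delta arithmetic follows from-to subtraction", {
  lib <- data.frame(compound_id = c("hi", "lo"),
                    smiles = c("Cc1ccccc1", "Clc1ccccc1"),
                    lyso_score = c(80, 30), stringsAsFactors = FALSE)
  mmps <- index_pairs(lib)
  phenyl <- mmps[mmps$constant == canonical_smiles("[At]c1ccccc1"), ]
  ## canonical direction puts the variables in lexicographic order; the
  ## delta is lyso(to) - lyso(from) under that orientation
  expect_equal(abs(phenyl$delta_lyso), 50)
  expect_equal(phenyl$delta_lyso,
               phenyl$lyso_to - phenyl$lyso_from)
})

test_that("transition classification switches exactly when 75 is crossed", {
  expect_identical(classify_transition(40, 90), "class_switch")
  expect_identical(classify_transition(10, 50), "nonlyso_to_nonlyso")
  expect_identical(classify_transition(75, 80), "lyso_to_lyso")
  expect_identical(classify_transition(74.99, 75), "class_switch")
  expect_identical(classify_transition(c(40, 10), c(90, 50)),
                   c("class_switch", "nonlyso_to_nonlyso"))
})

test_that("MMP and rule tables serialize to CSV", {
  dir <- withr::local_tempdir()
  lib <- data.frame(compound_id = c("a", "b", "c"),
                    smiles = c("Cc1ccccc1", "Clc1ccccc1", "Oc1ccccc1"),
                    lyso_score = c(80, 30, 55), stringsAsFactors = FALSE)
  mmps <- index_pairs(lib)
  rules <- derive_rules(mmps)
  paths <- write_mmpa_csv(mmps, rules, file.path(dir, "m.csv"),
                          file.path(dir, "r.csv"))
  back <- read.csv(paths$rules)
  expect_identical(nrow(back), nrow(rules))
  expect_true(all(grepl("^-?[0-9.]+(;-?[0-9.]+)*$", back$deltas)))
})
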