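test_that("simple molecules parse to the expected atoms and bonds", {
  m1 <- parse_smiles("C")
  expect_equal(nrow(m1$atoms), 1L)
  expect_equal(nrow(m1$bonds), 0L)
  m2 <- parse_smiles("CCO")
  expect_equal(nrow(m2$atoms), 3L)
  expect_equal(nrow(m2$bonds), 2L)
  expect_true(all(m2$bonds$kind == "single"))
  expect_equal(m2$atoms$element, c("C", "C", "O"))
})

test_that("malformed and chemically impossible SMILES raise parse errors", {
  for (bad in c("C((", "C1CC", "C)(", "", "[C", "C%1C",
                "C(Cl)(Cl)(Cl)(Cl)Cl")) {
    expect_error(parse_smiles(bad), class = "cdrnet_parse_error")
  }
})

test_that("benzene is perceived aromatic: all ring bonds on the aromatic channel", {
  g <- featurize(parse_smiles("c1ccccc1"))
  expect_equal(g$n_atoms, 6L)
  bonded <- which(apply(g$edge_tensor != 0, c(1, 2), any) &
                    upper.tri(matrix(TRUE, 6, 6)), arr.ind = TRUE)
  expect_equal(nrow(bonded), 6L)
  for (b in seq_len(nrow(bonded))) {
    slice <- g$edge_tensor[bonded[b, 1], bonded[b, 2], ]
    expect_equal(unname(slice[1:4]), c(0, 0, 0, 1))  # not single/double/triple
  }
})

test_that("ethanol has exactly two bonded pairs in the edge tensor", {
  g <- featurize(parse_smiles("CCO"))
  nz <- apply(g$edge_tensor != 0, c(1, 2), any)
  expect_equal(sum(nz[upper.tri(nz)]), 2L)
})

test_that("edge tensors are symmetric and zero on the diagonal across the pool", {
  for (s in cdrnet:::.smiles_pool[seq(1, 60, by = 7)]) {
    g <- featurize(parse_smiles(s))
    expect_equal(max(abs(g$edge_tensor - aperm(g$edge_tensor, c(2, 1, 3)))), 0)
    for (i in seq_len(g$n_atoms))
      expect_equal(sum(abs(g$edge_tensor[i, i, ])), 0)
  }
})

test_that("heavy-atom counts agree with an independent text-based count", {
  for (s in cdrnet:::.smiles_pool) {
    g <- featurize(parse_smiles(s))
    expect_equal(g$n_atoms, count_heavy_atoms_text(s), info = s)
  }
})

test_that("featurize is equivariant to atom relabeling", {
  set.seed(21)
  mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  g <- featurize(mol)
  n <- g$n_atoms
  for (rep in 1:5) {
    pm <- sample(n)                     # pm[new] = old
    inv <- order(pm)
    mol2 <- mol
    mol2$atoms <- mol$atoms[pm, , drop = FALSE]
    mol2$bonds$i <- inv[mol$bonds$i]
    mol2$bonds$j <- inv[mol$bonds$j]
    swap <- mol2$bonds$i > mol2$bonds$j
    tmp <- mol2$bonds$i[swap]
    mol2$bonds$i[swap] <- mol2$bonds$j[swap]
    mol2$bonds$j[swap] <- tmp
    g2 <- featurize(mol2)
    expect_equal(g2$node_features, g$node_features[pm, , drop = FALSE])
    expect_equal(g2$edge_tensor, g$edge_tensor[pm, pm, , drop = FALSE])
  }
})

test_that("schema without an 'other' bucket rejects unlisted elements", {
  sch <- feature_schema(elements = c("C", "O"), other_bucket = FALSE)
  expect_error(featurize(parse_smiles("CCN"), sch),
               class = "cdrnet_schema_error")
  expect_silent(featurize(parse_smiles("CCO"), sch))
})

test_that("drug tables round-trip through csv and smi formats", {
  df <- data.frame(drug_id = c("a", "b"), smiles = c("CCO", "c1ccccc1"),
                   stringsAsFactors = FALSE)
  f1 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f1, row.names = FALSE)
  expect_equal(read_drug_table(f1), df)
  f2 <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "c1ccccc1 b"), f2)
  got <- read_drug_table(f2)
  expect_equal(got$smiles, df$smiles)
  expect_equal(got$drug_id, df$drug_id)
})

test_that("canonical forms identify identical molecules across renderings", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_false(canonical_smiles("CCO") == canonical_smiles("CCN"))
})
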