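test_that("featurization recovers the expected topology of small molecules", {
  g <- featurize("c1ccccc1")
  expect_equal(g$n_heavy, 6L)
  expect_equal(nrow(g$edges), 6L)
  expect_true(all(g$nodes$aromatic))
  expect_true(all(g$nodes$in_ring))
  expect_true(all(g$edges$bond_type == 4L))

  g1 <- featurize("C")
  expect_equal(g1$n_heavy, 1L)
  expect_equal(nrow(g1$edges), 0L)
  expect_false(any(g1$nodes$aromatic))
  expect_equal(g1$nodes$n_heavy_neighbors, 0L)

  g2 <- featurize("C=O")
  expect_equal(g2$n_heavy, 2L)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$bond_type, 2L)
  expect_false(g2$edges$conjugated)
})

test_that("featurization is deterministic and SMILES-form invariant", {
  a <- featurize("c1ccccc1")
  b <- featurize("C1=CC=CC=C1")   # kekulized spelling of benzene
  expect_identical(atom_features(a), atom_features(b))
  expect_identical(bond_features(a), bond_features(b))
  expect_identical(a$smiles, b$smiles)
  expect_identical(atom_features(a), atom_features(featurize("c1ccccc1")))
})

test_that("featurization errors are loud and specific", {
  expect_error(featurize("C(XX"), "cannot parse")
  expect_error(featurize("[Na+].[Cl-]"), "multi-fragment")
  expect_error(featurize("C[Si](C)C"), "vocabulary")
  # extending the vocabulary admits the element
  g <- featurize("C[Si](C)C", element_vocabulary("Si"))
  expect_equal(sum(g$nodes$element == "Si"), 1L)
})

test_that("scaled features and invariants hold across generated molecules", {
  smis <- gen_molecules(15, max_heavy = 8, seed = 42)
  for (smi in smis) {
    g <- featurize(smi)
    X <- atom_features(g)
    expect_true(all(is.finite(X)))
    sc <- c(g$nodes$mass_scaled, g$nodes$vdw_radius_scaled,
            g$nodes$covalent_radius_scaled)
    expect_true(all(sc >= 0 & sc <= 1))
    # handshake: degrees sum to twice the edge count
    expect_equal(sum(g$nodes$n_heavy_neighbors), 2L * nrow(g$edges))
    expect_true(all(g$nodes$element_index >= 1 &
                    g$nodes$element_index <= length(g$vocabulary)))
    if (nrow(g$edges))
      expect_true(all(g$edges$i != g$edges$j))
    # no duplicate undirected bonds
    key <- paste(pmin(g$edges$i, g$edges$j), pmax(g$edges$i, g$edges$j))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("directed expansion doubles the undirected edge list", {
  g <- featurize("c1ccccc1")
  d <- to_directed(g)
  expect_equal(length(d$src), 12L)
  expect_equal(length(to_directed(featurize("C"))$src), 0L)
  smis <- gen_molecules(8, max_heavy = 7, seed = 3)
  for (smi in smis) {
    g <- featurize(smi)
    d <- to_directed(g)
    expect_equal(length(d$src), 2L * nrow(g$edges))
    # both directions of each bond share one feature record
    expect_equal(d$eidx[seq_len(nrow(g$edges))],
                 d$eidx[nrow(g$edges) + seq_len(nrow(g$edges))])
  }
})

test_that("molecule tables are read with skip-and-report semantics", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = paste0("m", 1:5),
                       smiles = c("CC", "CCO", "xxx(", "c1ccccc1", "CN"),
                       E_water = rnorm(5)), tf, row.names = FALSE)
  expect_message(tab <- read_molecule_table(tf), "1 row")
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "n_skipped"), 1L)

  write.csv(data.frame(a = 1), tf, row.names = FALSE)
  expect_error(read_molecule_table(tf), "columns")
  file.create(tf2 <- tempfile(fileext = ".csv"))
  writeLines("id,smiles", tf2)
  expect_error(read_molecule_table(tf2), "non-empty")
})

test_that("graph JSON serialization round-trips", {
  for (smi in c("CC(=O)N", "C")) {
    g <- featurize(smi)
    tf <- tempfile(fileext = ".json")
    write_mol_graph(g, tf)
    g2 <- read_mol_graph(tf)
    expect_equal(atom_features(g), atom_features(g2))
    expect_equal(bond_features(g), bond_features(g2))
    expect_identical(g$smiles, g2$smiles)
  }
})
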