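test_that("window score is 1 inside, 0 far outside, 0.5 at the edge", {
  w <- target_window(4.0, 5.0, steepness = 50)
  expect_equal(window_score(4.5, w), 1, tolerance = 1e-3)
  expect_equal(window_score(2.0, w), 0, tolerance = 1e-3)
  expect_equal(window_score(7.0, w), 0, tolerance = 1e-3)
  expect_equal(window_score(4.0, w), 0.5, tolerance = 1e-3)
  # monotone up to the midpoint, down after it
  xs <- seq(2, 4.5, by = 0.01)
  expect_true(all(diff(window_score(xs, w)) >= 0))
  xs <- seq(4.5, 7, by = 0.01)
  expect_true(all(diff(window_score(xs, w)) <= 0))
  # a 0.25 V window still scores ~1 at its midpoint at default steepness
  wn <- target_window(4.0, 4.25)
  expect_gt(window_score(4.125, wn), 0.99)
  expect_error(target_window(5, 4))
})

test_that("application window presets convert to the absolute scale", {
  aw <- application_windows()
  expect_named(aw, c("pedot", "ppt", "li_additive", "rfb_anolyte"))
  w <- window_to_absolute(aw$rfb_anolyte)
  expect_equal(c(w$lo, w$hi), c(4.08, 4.68))
  expect_equal(w$hi - w$lo, aw$rfb_anolyte$hi - aw$rfb_anolyte$lo)
  wppt <- window_to_absolute(aw$ppt)
  expect_equal(wppt$hi - wppt$lo, 0.25, tolerance = 1e-12)
})

test_that("graph mutations respect chemistry and constraints", {
  cfg <- evolution_config(seed = 1)
  set.seed(1)
  # add_atom on methane gives a two-heavy-atom skeleton
  r <- mutate_mol(smiles_to_edit_mol("C"), "add_atom", cfg)
  expect_true(r$accepted)
  expect_length(r$mol$elements, 2L)
  # removing the only atom is rejected, not an error
  r <- mutate_mol(smiles_to_edit_mol("C"), "remove_atom", cfg)
  expect_false(r$accepted)
  expect_match(r$reason, "empty")
  # the 15-heavy-atom cap rejects growth
  m15 <- smiles_to_edit_mol(paste(rep("C", 15), collapse = ""))
  r <- mutate_mol(m15, "add_atom", cfg)
  expect_false(r$accepted)
  expect_equal(r$reason, "size")
  # random mutations always yield valid molecules within constraints
  set.seed(7)
  mol <- smiles_to_edit_mol("CCO")
  for (k in 1:60) {
    r <- mutate_mol(mol, sample(redoxgnn:::.mutation_actions, 1), cfg)
    if (!r$accepted) next
    mol <- r$mol
    expect_true(isTRUE(redoxgnn:::.mol_valid(mol, cfg$allowed_elements,
                                             cfg$max_heavy_atoms)))
    smi <- edit_mol_to_smiles(mol)
    g <- featurize(smi)
    expect_lte(g$n_heavy, 15L)
    expect_true(all(g$nodes$element %in% cfg$allowed_elements))
  }
})

test_that("synthetic accessibility gate uses the reference scorer", {
  sc <- sa_score(c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"))
  expect_true(all(is.finite(sc)))
  expect_true(all(sc >= 1 & sc <= 10))
  g <- sa_gate("c1ccccc1", threshold = 4.5)
  expect_true(g$pass)
  expect_lt(g$score, 4.5)
  # threshold 0 fails everything
  expect_false(sa_gate("c1ccccc1", threshold = 0)$pass)
  # deterministic per canonical SMILES
  expect_identical(sa_score("c1ccccc1"), sa_score("C1=CC=CC=C1"))
  expect_true(is.na(sa_score("xx((")))
})

test_that("ensemble objective requires every member in-window", {
  w <- target_window(1.0, 2.0, 50)
  g <- featurize("CCO")
  # a synthetic truth with only an intercept predicts a constant for
  # every molecule and solvent: a controllable ensemble member
  mk <- function(val) synthetic_truth(
    ea_weights = c(intercept = val, N = 0, O = 0, F = 0, S = 0,
                   Cl = 0, Br = 0, aromatic = 0, ring = 0),
    solv_weight = 0, polz_weight = 0, noise_sd = 0)
  expect_equal(predict_potential(mk(1.5), g, "ACN"), 1.5)
  all_in <- lapply(rep(1.5, 5), mk)
  ob <- ensemble_objective(g, all_in, "ACN", w)
  expect_true(ob$accept)
  expect_equal(ob$score, 1, tolerance = 1e-3)
  # 4 of 5 inside is rejected regardless of the mean score
  one_out <- lapply(c(1.5, 1.5, 1.5, 1.5, 5.0), mk)
  ob2 <- ensemble_objective(g, one_out, "ACN", w)
  expect_false(ob2$accept)
  expect_error(ensemble_objective(g, list(), "ACN", w), "at least one")
})

test_that("the evolution loop finds candidates for an attainable window", {
  truth <- synthetic_truth(noise_sd = 0)
  # brute-force confirmation that the window is attainable: enumerate
  # the reachable neighborhood of the seed with the truth itself
  seed_smi <- "CCO"
  pool <- gen_molecules(40, max_heavy = 6, seed = 99)
  vals <- vapply(pool, function(s)
    synth_potential(featurize(s), "acetonitrile", truth)$e_red,
    numeric(1))
  tgt <- stats::median(vals)
  w <- target_window(tgt - 0.15, tgt + 0.15, 50)
  expect_gt(sum(vals >= w$lo & vals <= w$hi), 0)

  obj <- function(smi, g) {
    p <- synth_potential(g, "acetonitrile", truth)$e_red
    list(score = window_score(p, w), accept = p >= w$lo && p <= w$hi)
  }
  cfg <- evolution_config(population_size = 15, max_generations = 10,
                          max_heavy_atoms = 10, seed = 4)
  res <- evolve_loop(seed_smi, cfg, obj, use_sa_gate = FALSE)
  expect_gte(nrow(res), 1L)
  # every emitted candidate verifies against the truth and constraints
  for (k in seq_len(min(nrow(res), 10))) {
    g <- featurize(res$smiles[k])
    p <- synth_potential(g, "acetonitrile", truth)$e_red
    expect_true(p >= w$lo && p <= w$hi)
    expect_lte(g$n_heavy, 10L)
  }
  # determinism
  res2 <- evolve_loop(seed_smi, cfg, obj, use_sa_gate = FALSE)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # constant objective: loop terminates at max_generations
  resc <- evolve_loop("CC", evolution_config(population_size = 5,
                                             max_generations = 3,
                                             seed = 2),
                      function(smi, g) list(score = 1, accept = FALSE),
                      use_sa_gate = FALSE)
  expect_equal(max(attr(resc, "log")$generation), 3L)
  expect_error(evolve_loop("xx((", cfg, obj, use_sa_gate = FALSE),
               "no valid seed")
})

test_that("shrinking the window never enlarges the accepted set", {
  truth <- synthetic_truth(noise_sd = 0)
  pool <- gen_molecules(25, max_heavy = 6, seed = 5)
  vals <- vapply(pool, function(s)
    synth_potential(featurize(s), "acetonitrile", truth)$e_red,
    numeric(1))
  mid <- stats::median(vals)
  wide <- target_window(mid - 0.5, mid + 0.5)
  narrow <- target_window(mid - 0.2, mid + 0.2)
  acc_wide <- pool[vals >= wide$lo & vals <= wide$hi]
  acc_narrow <- pool[vals >= narrow$lo & vals <= narrow$hi]
  expect_true(all(acc_narrow %in% acc_wide))
})
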