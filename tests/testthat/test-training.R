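test_that("molecule-level split has exact sizes and is leak-free", {
  ids <- sprintf("m%03d", 1:100)
  sp <- split_molecules(ids, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(as.integer(table(sp)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  expect_identical(sp, split_molecules(ids, c(0.8, 0.1, 0.1), seed = 7))
  expect_false(identical(sp, split_molecules(ids, c(0.8, 0.1, 0.1),
                                             seed = 8)))
  # disjoint and exhaustive by construction of the mapping
  expect_setequal(names(sp), ids)
  expect_true(all(sp %in% c("train", "val", "test")))
  # sizes within 1 of exact fractions for awkward n
  for (n in c(11, 57, 103)) {
    sp2 <- split_molecules(sprintf("x%d", 1:n), c(0.8, 0.1, 0.1), 1)
    expect_true(all(abs(table(sp2)[c("train", "val", "test")] -
                          n * c(0.8, 0.1, 0.1)) <= 1))
  }
  expect_error(split_molecules(letters[1:5]), "at least 10")
  expect_error(split_molecules(c(ids, ids[1])), "unique")
})

test_that("combined loss sums per-dimension masked MAEs", {
  expect_equal(combined_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(combined_loss(matrix(c(0, 1)), matrix(c(1, 1))), 0.5)
  # two dimensions with MAE 0.5 each sum to 1
  p <- cbind(c(0, 1), c(2, 3)); t2 <- cbind(c(1, 1), c(2.5, 3.5))
  expect_equal(combined_loss(p, t2), 1.0)
  # masked rows never change the loss
  p3 <- rbind(p, c(99, 99)); t3 <- rbind(t2, c(NA, NA))
  expect_equal(combined_loss(p3, t3), combined_loss(p, t2))
  expect_error(combined_loss(matrix(1), matrix(NA_real_)), "unmasked")
})

test_that("metrics match their definitions", {
  obs <- c(1, 2, 3, 4)
  m <- redox_metrics(obs, obs)
  expect_equal(m$mae, 0); expect_equal(m$r2, 1)
  # mean-value predictor has R^2 = 0
  m0 <- redox_metrics(rep(mean(obs), 4), obs)
  expect_equal(m0$r2, 0)
  expect_equal(redox_metrics(c(1, 2), c(2, 2))$mae, 0.5)
  # constant targets: R^2 undefined
  expect_true(is.na(redox_metrics(c(1, 2), c(2, 2))$r2))
  # per-solvent breakdown and unweighted averaging
  m2 <- redox_metrics(c(1, 2, 4, 8), c(1, 2, 5, 10),
                      c("a", "a", "b", "b"))
  expect_equal(nrow(m2$per_solvent), 2)
  expect_equal(m2$mae, mean(c(0, 1.5)))
})

test_that("training learns a learnable synthetic truth and is reproducible", {
  truth <- synthetic_truth(noise_sd = 0.05, seed = 5)
  tab <- gen_dataset(40, truth = truth, max_heavy = 7)
  cfg <- tiny_config("sd")
  ctl <- train_control(epochs = 6, batch_size = 16, learning_rate = 3e-3,
                       seed = 2)
  fit <- redox_gnn(tab, config = cfg, control = ctl)
  expect_s3_class(fit, "redox_gnn")
  expect_equal(nrow(fit$history), 6)
  # learning curve decreases on learnable truth
  expect_lt(fit$history$val_loss[6], fit$history$val_loss[1])
  # determinism: same seed, same data -> identical loss history
  fit2 <- redox_gnn(tab, config = cfg, control = ctl)
  expect_identical(fit$history, fit2$history)

  # epochs = 0 returns initial parameters and empty history
  ctl0 <- train_control(epochs = 0, seed = 2)
  fit0 <- redox_gnn(tab, config = cfg, control = ctl0)
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$model$params, mpnn_init(cfg, seed = 2)$params)

  # prediction interface
  pr <- predict(fit, c("CCO", "CCN"), solvent = "water")
  expect_equal(nrow(pr), 2)
  expect_equal(pr$reduction_potential,
               pr$ea_component + pr$solvent_component)
  rs <- residuals(fit, "test")
  expect_true(all(is.finite(rs)))
})

test_that("vs variant trains on the multi-output loss", {
  truth <- synthetic_truth(noise_sd = 0.05, seed = 6)
  tab <- gen_dataset(30, truth = truth, max_heavy = 6)
  cfg <- tiny_config("vs")
  ctl <- train_control(epochs = 4, batch_size = 16, learning_rate = 3e-3,
                       seed = 3)
  fit <- redox_gnn(tab, variant = "vs", config = cfg, control = ctl)
  expect_lt(fit$history$val_loss[4], fit$history$val_loss[1])
  pr <- predict(fit, "CCO")
  expect_true(all(five_solvents %in% names(pr)))
})

test_that("solvent exclusion removes every withheld record from training", {
  truth <- synthetic_truth(noise_sd = 0.05, seed = 7)
  tab <- gen_dataset(30, truth = truth, max_heavy = 6)
  cfg <- tiny_config("sd")
  ctl <- train_control(epochs = 2, batch_size = 16, learning_rate = 1e-3,
                       seed = 4)
  res <- loso_protocol(tab, "water", config = cfg, control = ctl)
  expect_s3_class(res, "loso_result")
  expect_equal(unname(res$audit["water"]), 0L)
  expect_gt(sum(res$audit), 0L)
  expect_equal(res$withheld, "water")
  expect_true(all(res$metrics$per_solvent$solvent == "water"))
  expect_error(loso_protocol(tab, "benzene-xyz", config = cfg,
                             control = ctl), "unknown solvent")
})

test_that("checkpoints round-trip through save/load", {
  truth <- synthetic_truth(noise_sd = 0.05, seed = 8)
  tab <- gen_dataset(30, truth = truth, max_heavy = 6)
  cfg <- tiny_config("sd")
  ctl <- train_control(epochs = 2, batch_size = 16, seed = 5)
  fit <- redox_gnn(tab, config = cfg, control = ctl)
  dir <- tempfile()
  save_redox_gnn(fit, dir)
  fit2 <- load_redox_gnn(dir)
  g <- featurize("CCO")
  expect_equal(forward_sd(fit2$model, g, "ACN")$reduction_potential,
               forward_sd(fit$model, g, "ACN")$reduction_potential,
               tolerance = 1e-12)
})
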