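test_that("analytic gradients match central finite differences", {
  set.seed(42)
  g <- featurize("CC(=O)c1ccc(N)cc1")
  pg <- redoxgnn:::.prep_graph(g)
  sdesc <- descriptor_vector("ACN")
  eps <- 1e-6

  for (variant in c("sd", "vs")) {
    mod <- mpnn_init(tiny_config(variant), seed = 3)
    if (variant == "sd") {
      lossf <- function(m) {
        fw <- redoxgnn:::.mpnn_forward(m, pg, sdesc)
        0.7 * fw$ea + 1.3 * fw$solvent_component
      }
      fw <- redoxgnn:::.mpnn_forward(mod, pg, sdesc, cache = TRUE)
      grads <- redoxgnn:::.mpnn_backward(
        mod, pg, fw, list(d_ea = 0.7, d_solv = 1.3),
        redoxgnn:::.zero_like(mod$params))
    } else {
      w <- c(0.3, -0.2, 0.5, 1.1, -0.7)
      lossf <- function(m) {
        fw <- redoxgnn:::.mpnn_forward(m, pg)
        sum(fw$potentials * w) + 0.4 * fw$ea
      }
      fw <- redoxgnn:::.mpnn_forward(mod, pg, cache = TRUE)
      grads <- redoxgnn:::.mpnn_backward(
        mod, pg, fw, list(d_ea = 0.4, d_pots = w),
        redoxgnn:::.zero_like(mod$params))
    }
    for (nm in names(mod$params)) {
      pm <- mod$params[[nm]]
      for (i in sample(length(pm), min(3L, length(pm)))) {
        m2 <- mod
        m2$params[[nm]][i] <- pm[i] + eps; fp <- lossf(m2)
        m2$params[[nm]][i] <- pm[i] - eps; fm <- lossf(m2)
        num <- (fp - fm) / (2 * eps)
        ana <- grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-7, abs(num) + abs(ana)), 1e-5)
      }
    }
  }
})

test_that("zero message weights leave states unchanged (residual identity)", {
  mod <- mpnn_init(tiny_config("sd"), seed = 1)
  for (nm in c("Wm1", "bm1", "Wm2", "bm2", "Wme"))
    mod$params[[nm]] <- mod$params[[nm]] * 0
  g <- featurize("CCOC")
  s0 <- message_pass(mod, g, state = NULL)  # init + one zeroed iteration
  s1 <- message_pass(mod, g, state = s0)
  s2 <- message_pass(mod, g, state = s1)
  expect_equal(s0, s1)
  expect_equal(s1, s2)
})

test_that("a neighborless node is untouched by message passing", {
  mod <- mpnn_init(tiny_config("sd"), seed = 2)
  g <- featurize("C")
  s0 <- redoxgnn:::.init_state(redoxgnn:::.prep_graph(g), mod$params)
  s1 <- message_pass(mod, g, state = s0)
  expect_identical(s0$H, s1$H)
})

test_that("forward passes are deterministic and satisfy the variant contracts", {
  g <- featurize("O=C1C=CC(=O)C=C1")   # quinone
  sd <- mpnn_init(tiny_config("sd"), seed = 5)
  p1 <- forward_sd(sd, g, "ACN")
  p2 <- forward_sd(sd, g, "ACN")
  expect_identical(p1, p2)
  # the summation contract is exact
  expect_identical(p1$reduction_potential,
                   p1$ea_component + p1$solvent_component)
  # the EA head sees no solvent input
  for (s in five_solvents)
    expect_identical(forward_sd(sd, g, s)$ea_component, p1$ea_component)
  # identical descriptors give identical predictions
  twin <- solvent_spec("twin", get_solvent("ACN")$epsilon,
                       get_solvent("ACN")$refractive_index)
  expect_equal(forward_sd(sd, g, twin)$reduction_potential,
               p1$reduction_potential)

  vs <- mpnn_init(tiny_config("vs"), seed = 5)
  pv <- forward_vs(vs, g)
  expect_length(pv$potentials, 5L)
  expect_named(pv$potentials, five_solvents)
  # sd queried on the five training solvents yields a comparable 5-vector
  sd5 <- vapply(five_solvents, function(s)
    forward_sd(sd, g, s)$reduction_potential, numeric(1))
  expect_length(sd5, 5L)
})

test_that("readout and full model are permutation invariant", {
  set.seed(99)
  sd <- mpnn_init(tiny_config("sd"), seed = 7)
  vs <- mpnn_init(tiny_config("vs"), seed = 7)
  smis <- gen_molecules(12, max_heavy = 9, seed = 12)
  for (smi in smis) {
    g <- featurize(smi)
    gp <- permute_graph(g)
    d1 <- forward_sd(sd, g, "DMSO")$reduction_potential
    d2 <- forward_sd(sd, gp, "DMSO")$reduction_potential
    expect_lt(abs(d1 - d2), 1e-4)
    v1 <- forward_vs(vs, g)$potentials
    v2 <- forward_vs(vs, gp)$potentials
    expect_lt(max(abs(v1 - v2)), 1e-4)
  }
  # readout output shape and empty-set error
  st <- message_pass(sd, featurize("CCO"))
  expect_length(readout(sd, st), tiny_config()$graph_dim)
  expect_error(readout(sd, list(H = matrix(0, 0, 8),
                                E = matrix(0, 0, 6))), "empty")
  # duplicated disjoint copies still pool to the right shape
  g <- featurize("CC")
  pg <- redoxgnn:::.prep_graph(g)
  pg2 <- list(X = rbind(pg$X, pg$X), B = rbind(pg$B, pg$B),
              src = c(pg$src, pg$src + 2L), dst = c(pg$dst, pg$dst + 2L),
              eidx = c(pg$eidx, pg$eidx + 1L), n = 4L, m = 2L)
  fw <- redoxgnn:::.mpnn_forward(sd, pg2, descriptor_vector("ACN"))
  expect_true(is.finite(fw$reduction_potential))
})

test_that("one optimizer step on a single example reduces its loss", {
  mod <- mpnn_init(tiny_config("sd"), seed = 31)
  g <- redoxgnn:::.prep_graph(featurize("CCO"))
  rec <- list(list(id = "m", solvent = "water",
                   sdesc = descriptor_vector("water"), target = 1.5,
                   ea = 1.0))
  graphs <- list(m = g)
  ctl <- train_control(epochs = 1, learning_rate = 1e-3, seed = 1)
  opt <- redoxgnn:::.adamw_init(mod$params)
  st <- redoxgnn:::.train_batch(mod, rec, graphs, opt, ctl)
  fw0 <- redoxgnn:::.forward_records(mod, rec, graphs)
  fw1 <- redoxgnn:::.forward_records(st$model, rec, graphs)
  expect_lt(combined_loss(fw1$pred, fw1$target),
            combined_loss(fw0$pred, fw0$target))
})

test_that("configuration constraints are enforced", {
  expect_error(model_config(graph_dim = 10, n_attention_heads = 4))
  expect_error(model_config(n_message_iterations = 0))
  expect_error(forward_sd(mpnn_init(tiny_config("vs"), 1),
                          featurize("C"), "ACN"))
})
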