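#' Model configuration for the reduction-potential network
#'
#' Architecture hyperparameters of the residual message-passing network
#' with attention (Set Transformer) readout. Two output variants exist:
#' `"vs"` emits a fixed-order vector of per-solvent potentials plus the
#' electron affinity; `"sd"` emits a single potential as the sum of a
#' solvent-independent electron-affinity head and a solvent-dependent
#' head that receives the two solvent descriptors, which is what
#' enables prediction in solvents never seen during training.
#'
#' @param variant `"sd"` (solvent description) or `"vs"` (vector of
#'   solvents).
#' @param n_message_iterations Number of message-passing iterations
#'   (default 6).
#' @param node_dim,edge_dim,graph_dim Latent sizes (defaults 128, 128,
#'   256).
#' @param n_attention_heads Attention heads in the pooling layer; must
#'   divide `graph_dim`.
#' @param head_hidden Hidden width of the output MLP heads.
#' @param solvents Character vector naming the fixed solvent order of
#'   the `"vs"` output (and the default training solvents).
#' @param descriptor_transform Solvent descriptor transform, see
#'   [descriptor_vector()].
#' @param vocabulary Element vocabulary, see [element_vocabulary()].
#' @return A list of class `"mpnn_config"`.
#' @export
model_config <- function(variant = c("sd", "vs"),
                         n_message_iterations = 6L,
                         node_dim = 128L, edge_dim = 128L,
                         graph_dim = 256L,
                         n_attention_heads = 4L,
                         head_hidden = 64L,
                         solvents = c("acetonitrile", "water",
                                      "tetrahydrofuran",
                                      "dimethylsulfoxide",
                                      "dimethylformamide"),
                         descriptor_transform = c("minmax", "onsager"),
                         vocabulary = element_vocabulary()) {
  variant <- match.arg(variant)
  descriptor_transform <- match.arg(descriptor_transform)
  stopifnot(n_message_iterations >= 1, node_dim > 0, edge_dim > 0,
            graph_dim > 0, n_attention_heads >= 1,
            graph_dim %% n_attention_heads == 0, head_hidden > 0,
            length(solvents) >= 1)
  structure(list(variant = variant,
                 n_message_iterations = as.integer(n_message_iterations),
                 node_dim = as.integer(node_dim),
                 edge_dim = as.integer(edge_dim),
                 graph_dim = as.integer(graph_dim),
                 n_attention_heads = as.integer(n_attention_heads),
                 head_hidden = as.integer(head_hidden),
                 solvents = solvents,
                 n_solvents = length(solvents),
                 descriptor_transform = descriptor_transform,
                 vocabulary = vocabulary),
            class = "mpnn_config")
}

.runif_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

#' Initialize network parameters
#'
#' Fan-in scaled uniform initialization under a recorded seed.
#'
#' @param config An [model_config()] object.
#' @param seed Integer RNG seed.
#' @return An object of class `"mpnn_model"`: list with `params`,
#'   `config`, `seed`.
#' @export
mpnn_init <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "mpnn_config"))
  set.seed(seed)
  fa <- length(config$vocabulary) + 7L
  fb <- 6L
  dn <- config$node_dim; de <- config$edge_dim; dg <- config$graph_dim
  hd <- config$head_hidden
  p <- list(
    Wxn = .runif_mat(fa, dn), bxn = numeric(dn),
    Wxe = .runif_mat(fb, de), bxe = numeric(de),
    Wm1 = .runif_mat(2L * dn + de, dn), bm1 = numeric(dn),
    Wm2 = .runif_mat(dn, dn), bm2 = numeric(dn),
    Wme = .runif_mat(dn, de),
    Wpn = .runif_mat(dn, dg), Wpe = .runif_mat(de, dg),
    q = .runif_mat(1L, dg) * sqrt(dg),
    Wq = .runif_mat(dg, dg), Wk = .runif_mat(dg, dg),
    Wv = .runif_mat(dg, dg), Wo = .runif_mat(dg, dg), bo = numeric(dg),
    We1 = .runif_mat(dg, hd), be1 = numeric(hd),
    we2 = .runif_mat(hd, 1L), be2 = numeric(1L)
  )
  if (config$variant == "sd") {
    p$Ws1 <- .runif_mat(dg + 2L, hd); p$bs1 <- numeric(hd)
    p$ws2 <- .runif_mat(hd, 1L); p$bs2 <- numeric(1L)
  } else {
    p$Wv1 <- .runif_mat(dg, hd); p$bv1 <- numeric(hd)
    p$wv2 <- .runif_mat(hd, config$n_solvents)
    p$bv2 <- numeric(config$n_solvents)
  }
  structure(list(params = p, config = config, seed = seed),
            class = "mpnn_model")
}

#' @export
print.mpnn_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, integer(1)))
  cat("mpnn_model (GNN-", toupper(cfg$variant), "): ",
      cfg$n_message_iterations, " message iterations, node/edge/graph dims ",
      cfg$node_dim, "/", cfg$edge_dim, "/", cfg$graph_dim, ", ",
      cfg$n_attention_heads, " attention heads, ", np, " parameters\n",
      sep = "")
  invisible(x)
}

# Preprocess a mol_graph into the tensors the network consumes.
.prep_graph <- function(g) {
  d <- to_directed(g)
  list(X = atom_features(g), B = bond_features(g),
       src = d$src, dst = d$dst, eidx = d$eidx,
       n = g$n_heavy, m = nrow(g$edges))
}

.index_add <- function(M, idx, X) {
  if (length(idx) == 0L) return(M)
  rs <- rowsum(X, group = idx)
  rows <- as.integer(rownames(rs))
  M[rows, ] <- M[rows, , drop = FALSE] + rs
  M
}

#' One message-passing iteration
#'
#' Computes one residual update: each directed edge carries a message
#' computed by a two-layer MLP from (source state, target state, edge
#' state); messages are sum-aggregated per receiving node and added to
#' the node state, and the two directed messages of each bond update
#' its edge state residually.
#'
#' @param model An [mpnn_init()]ed model.
#' @param g A `mol_graph` (or the result of the internal graph prep).
#' @param state List with matrices `H` (nodes x node_dim) and `E`
#'   (edges x edge_dim); `NULL` initializes from the input projections.
#' @return Updated `state` list.
#' @export
message_pass <- function(model, g, state = NULL) {
  pg <- if (inherits(g, "mol_graph")) .prep_graph(g) else g
  p <- model$params
  if (is.null(state)) state <- .init_state(pg, p)
  .message_pass_one(state, pg, p)$state
}

.init_state <- function(pg, p) {
  H <- sweep(pg$X %*% p$Wxn, 2, p$bxn, "+")
  E <- if (pg$m > 0L) sweep(pg$B %*% p$Wxe, 2, p$bxe, "+")
       else matrix(0, 0L, ncol(p$Wxe))
  list(H = H, E = E)
}

.message_pass_one <- function(state, pg, p) {
  H <- state$H; E <- state$E
  if (pg$m == 0L)
    return(list(state = state, cache = NULL))
  C <- cbind(H[pg$src, , drop = FALSE], H[pg$dst, , drop = FALSE],
             E[pg$eidx, , drop = FALSE])
  Z <- pmax(sweep(C %*% p$Wm1, 2, p$bm1, "+"), 0)
  M <- sweep(Z %*% p$Wm2, 2, p$bm2, "+")
  Hn <- .index_add(H, pg$dst, M)
  m <- pg$m
  Msum <- M[seq_len(m), , drop = FALSE] + M[m + seq_len(m), , drop = FALSE]
  En <- E + Msum %*% p$Wme
  list(state = list(H = Hn, E = En),
       cache = list(C = C, Z = Z, Msum = Msum))
}

#' Attention (Set Transformer) readout
#'
#' Pools the final node and edge states into a fixed-size graph vector
#' by multihead attention of a learned seed query over the joint set of
#' projected node and edge states. The output is invariant to node and
#' edge ordering.
#'
#' @param model An `mpnn_model`.
#' @param state State list from [message_pass()].
#' @return Numeric vector of length `graph_dim`.
#' @export
readout <- function(model, state) {
  if (nrow(state$H) == 0L) stop("cannot pool an empty set")
  .readout_fwd(state, model$params, model$config)$g
}

.readout_fwd <- function(state, p, cfg) {
  S <- rbind(state$H %*% p$Wpn,
             if (nrow(state$E) > 0L) state$E %*% p$Wpe)
  K <- S %*% p$Wk; Vv <- S %*% p$Wv; Q <- p$q %*% p$Wq
  Hh <- cfg$n_attention_heads
  dh <- cfg$graph_dim %/% Hh
  A <- matrix(0, nrow(S), Hh)
  O <- matrix(0, 1L, cfg$graph_dim)
  for (h in seq_len(Hh)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    l <- (K[, idx, drop = FALSE] %*% t(Q[, idx, drop = FALSE])) / sqrt(dh)
    a <- exp(l - max(l)); a <- a / sum(a)
    A[, h] <- a
    O[, idx] <- t(a) %*% Vv[, idx, drop = FALSE]
  }
  g <- sweep(O %*% p$Wo, 2, p$bo, "+")
  list(g = drop(g), cache = list(S = S, K = K, Vv = Vv, Q = Q,
                                 A = A, O = O))
}

.mlp2_fwd <- function(x, W1, b1, w2, b2) {
  u <- pmax(sweep(x %*% W1, 2, b1, "+"), 0)
  list(y = drop(sweep(u %*% w2, 2, b2, "+")), u = u)
}

# Full forward pass. sdesc: numeric(2) solvent descriptor (sd variant)
# or NULL (vs). Returns outputs and, if cache=TRUE, everything needed
# for the backward pass.
.mpnn_forward <- function(model, pg, sdesc = NULL, cache = FALSE) {
  p <- model$params; cfg <- model$config
  state <- .init_state(pg, p)
  caches <- vector("list", cfg$n_message_iterations)
  states <- if (cache) vector("list", cfg$n_message_iterations) else NULL
  for (t in seq_len(cfg$n_message_iterations)) {
    if (cache) states[[t]] <- state
    step <- .message_pass_one(state, pg, p)
    state <- step$state
    if (cache) caches[t] <- list(step$cache)
  }
  ro <- .readout_fwd(state, p, cfg)
  gvec <- matrix(ro$g, 1L)
  ea_h <- .mlp2_fwd(gvec, p$We1, p$be1, p$we2, p$be2)
  out <- list(ea = ea_h$y)
  if (cfg$variant == "sd") {
    if (is.null(sdesc)) stop("sd variant requires a solvent descriptor")
    gs <- cbind(gvec, matrix(sdesc, 1L))
    sv_h <- .mlp2_fwd(gs, p$Ws1, p$bs1, p$ws2, p$bs2)
    out$solvent_component <- sv_h$y
    out$reduction_potential <- ea_h$y + sv_h$y
  } else {
    vs_h <- .mlp2_fwd(gvec, p$Wv1, p$bv1, p$wv2, p$bv2)
    out$potentials <- vs_h$y
  }
  if (cache)
    out$cache <- list(state = state, states = states, mp = caches,
                      ro = ro$cache, gvec = gvec, ea_u = ea_h$u,
                      sv_u = if (cfg$variant == "sd") sv_h$u,
                      vs_u = if (cfg$variant == "vs") vs_h$u,
                      gs = if (cfg$variant == "sd") gs,
                      sdesc = sdesc)
  out
}

.zero_like <- function(p) lapply(p, function(x) x * 0)

.mlp2_bwd <- function(x, u, W1, w2, dy, grads, nm) {
  dy <- matrix(dy, 1L)
  grads[[nm[3]]] <- grads[[nm[3]]] + t(u) %*% dy
  grads[[nm[4]]] <- grads[[nm[4]]] + drop(dy)
  du <- (dy %*% t(w2)) * (u > 0)
  grads[[nm[1]]] <- grads[[nm[1]]] + t(x) %*% du
  grads[[nm[2]]] <- grads[[nm[2]]] + drop(du)
  list(grads = grads, dx = du %*% t(W1))
}

# Backward pass for one record. d_out: list with d_ea and (sd) d_solv
# or (vs) d_pots. Accumulates into `grads` (a .zero_like of params).
.mpnn_backward <- function(model, pg, fw, d_out, grads) {
  p <- model$params; cfg <- model$config
  ca <- fw$cache
  dg_vec <- matrix(0, 1L, cfg$graph_dim)

  bk <- .mlp2_bwd(ca$gvec, ca$ea_u, p$We1, p$we2, d_out$d_ea, grads,
                  c("We1", "be1", "we2", "be2"))
  grads <- bk$grads; dg_vec <- dg_vec + bk$dx

  if (cfg$variant == "sd") {
    bk <- .mlp2_bwd(ca$gs, ca$sv_u, p$Ws1, p$ws2, d_out$d_solv, grads,
                    c("Ws1", "bs1", "ws2", "bs2"))
    grads <- bk$grads
    dg_vec <- dg_vec + bk$dx[, seq_len(cfg$graph_dim), drop = FALSE]
  } else {
    bk <- .mlp2_bwd(ca$gvec, ca$vs_u, p$Wv1, p$wv2, d_out$d_pots, grads,
                    c("Wv1", "bv1", "wv2", "bv2"))
    grads <- bk$grads; dg_vec <- dg_vec + bk$dx
  }

  # readout backward
  ro <- ca$ro
  grads$Wo <- grads$Wo + t(ro$O) %*% dg_vec
  grads$bo <- grads$bo + drop(dg_vec)
  dO <- dg_vec %*% t(p$Wo)
  Hh <- cfg$n_attention_heads
  dh <- cfg$graph_dim %/% Hh
  N <- nrow(ro$S)
  dK <- matrix(0, N, cfg$graph_dim)
  dV <- matrix(0, N, cfg$graph_dim)
  dQ <- matrix(0, 1L, cfg$graph_dim)
  for (h in seq_len(Hh)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    a <- ro$A[, h]
    do_h <- dO[, idx, drop = FALSE]
    dV[, idx] <- a %*% do_h
    da <- ro$Vv[, idx, drop = FALSE] %*% t(do_h)
    dl <- a * (drop(da) - sum(a * drop(da)))
    dK[, idx] <- (dl %*% ro$Q[, idx, drop = FALSE]) / sqrt(dh)
    dQ[, idx] <- (matrix(dl, 1L) %*% ro$K[, idx, drop = FALSE]) / sqrt(dh)
  }
  grads$Wk <- grads$Wk + t(ro$S) %*% dK
  grads$Wv <- grads$Wv + t(ro$S) %*% dV
  dS <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads$Wq <- grads$Wq + t(p$q) %*% dQ
  grads$q <- grads$q + dQ %*% t(p$Wq)

  n <- pg$n; m <- pg$m
  dSn <- dS[seq_len(n), , drop = FALSE]
  Hfin <- ca$state$H; Efin <- ca$state$E
  grads$Wpn <- grads$Wpn + t(Hfin) %*% dSn
  dH <- dSn %*% t(p$Wpn)
  if (m > 0L) {
    dSe <- dS[n + seq_len(m), , drop = FALSE]
    grads$Wpe <- grads$Wpe + t(Efin) %*% dSe
    dE <- dSe %*% t(p$Wpe)
  } else dE <- matrix(0, 0L, cfg$edge_dim)

  # message-passing backward (reverse through the iterations)
  for (t in rev(seq_len(cfg$n_message_iterations))) {
    mc <- ca$mp[[t]]
    if (is.null(mc)) next  # zero-edge graph: identity step
    dM <- matrix(0, 2L * m, cfg$node_dim)
    dM <- dM + dH[pg$dst, , drop = FALSE]          # node residual
    dMsum <- dE %*% t(p$Wme)
    grads$Wme <- grads$Wme + t(mc$Msum) %*% dE
    dM[seq_len(m), ] <- dM[seq_len(m), , drop = FALSE] + dMsum
    dM[m + seq_len(m), ] <- dM[m + seq_len(m), , drop = FALSE] + dMsum
    grads$Wm2 <- grads$Wm2 + t(mc$Z) %*% dM
    grads$bm2 <- grads$bm2 + colSums(dM)
    dZ <- (dM %*% t(p$Wm2)) * (mc$Z > 0)
    grads$Wm1 <- grads$Wm1 + t(mc$C) %*% dZ
    grads$bm1 <- grads$bm1 + colSums(dZ)
    dC <- dZ %*% t(p$Wm1)
    dn <- cfg$node_dim
    dH <- .index_add(dH, pg$src, dC[, seq_len(dn), drop = FALSE])
    dH <- .index_add(dH, pg$dst, dC[, dn + seq_len(dn), drop = FALSE])
    dE <- .index_add(dE, pg$eidx,
                     dC[, 2L * dn + seq_len(cfg$edge_dim), drop = FALSE])
  }

  # input projections
  grads$Wxn <- grads$Wxn + t(pg$X) %*% dH
  grads$bxn <- grads$bxn + colSums(dH)
  if (m > 0L) {
    grads$Wxe <- grads$Wxe + t(pg$B) %*% dE
    grads$bxe <- grads$bxe + colSums(dE)
  }
  grads
}

#' Forward pass, solvent-description variant (GNN-SD)
#'
#' Predicts the reduction potential of a molecule in a solvent as the
#' exact sum of a solvent-independent electron-affinity component and a
#' solvent-dependent component computed from the graph vector
#' concatenated with the solvent descriptor pair.
#'
#' @param model An `mpnn_model` with `variant = "sd"`.
#' @param g A `mol_graph` (from [featurize()]).
#' @param solvent A solvent name or [solvent_spec()].
#' @param registry Solvent registry for name lookup.
#' @return A list of class `"redox_prediction"` with `ea_component`,
#'   `solvent_component`, `reduction_potential` (all eV) and `variant`.
#' @export
forward_sd <- function(model, g, solvent,
                       registry = solvent_registry()) {
  stopifnot(inherits(model, "mpnn_model"),
            model$config$variant == "sd")
  sdesc <- descriptor_vector(get_solvent(solvent, registry),
                             model$config$descriptor_transform)
  pg <- if (inherits(g, "mol_graph")) .prep_graph(g) else g
  fw <- .mpnn_forward(model, pg, sdesc)
  structure(list(ea_component = fw$ea,
                 solvent_component = fw$solvent_component,
                 reduction_potential = fw$reduction_potential,
                 variant = "sd"),
            class = "redox_prediction")
}

#' Forward pass, vector-of-solvents variant (GNN-VS)
#'
#' @param model An `mpnn_model` with `variant = "vs"`.
#' @param g A `mol_graph`.
#' @return A list of class `"redox_prediction"` with `ea_component`
#'   and the named `potentials` vector (fixed solvent order), all eV.
#' @export
forward_vs <- function(model, g) {
  stopifnot(inherits(model, "mpnn_model"),
            model$config$variant == "vs")
  pg <- if (inherits(g, "mol_graph")) .prep_graph(g) else g
  fw <- .mpnn_forward(model, pg)
  structure(list(ea_component = fw$ea,
                 potentials = stats::setNames(fw$potentials,
                                              model$config$solvents),
                 variant = "vs"),
            class = "redox_prediction")
}

#' @export
print.redox_prediction <- function(x, ...) {
  if (x$variant == "sd") {
    cat(sprintf("EA %.4f eV + solvent %.4f eV = E_red %.4f eV\n",
                x$ea_component, x$solvent_component,
                x$reduction_potential))
  } else {
    cat(sprintf("EA %.4f eV; per-solvent potentials (eV):\n",
                x$ea_component))
    print(round(x$potentials, 4))
  }
  invisible(x)
}
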