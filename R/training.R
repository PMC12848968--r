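#' Training control parameters
#'
#' Defaults follow the published recipe: 60 epochs, batch size 32,
#' AdamW with learning rate 1e-4 and weight decay 1e-5, and an
#' 80/10/10 molecule-level train/validation/test split.
#'
#' @param epochs Number of epochs.
#' @param batch_size Batch size.
#' @param learning_rate AdamW learning rate.
#' @param weight_decay AdamW (decoupled) weight decay.
#' @param ratios Length-3 train/validation/test fractions summing to 1.
#' @param seed Integer seed controlling initialization, splitting and
#'   shuffling.
#' @param grad_clip Optional gradient-norm clip (`Inf` disables; off by
#'   default).
#' @param verbose Print per-epoch losses.
#' @return A list of class `"train_control"`.
#' @export
train_control <- function(epochs = 60L, batch_size = 32L,
                          learning_rate = 1e-4, weight_decay = 1e-5,
                          ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          grad_clip = Inf, verbose = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0, length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, ratios = ratios,
                 seed = as.integer(seed), grad_clip = grad_clip,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Molecule-level train/validation/test split
#'
#' Assigns whole molecules to partitions, so every record of a molecule
#' (all solvents, the electron affinity) lands in exactly one
#' partition — the leakage guard that makes the test set a fair
#' assessment of generalization to new molecules. Deterministic for a
#' fixed seed; partition sizes are within one of the exact fractions.
#'
#' @param ids Character vector of molecule ids (>= 10).
#' @param ratios Train/validation/test fractions.
#' @param seed RNG seed.
#' @return Named character vector mapping each id to
#'   `"train"`, `"val"` or `"test"`.
#' @export
split_molecules <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  n <- length(ids)
  if (n < 10L) stop("need at least 10 molecule ids to split")
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  set.seed(seed)
  perm <- sample(n)
  cuts <- round(cumsum(ratios) * n)
  part <- character(n)
  part[perm[seq_len(cuts[1])]] <- "train"
  part[perm[(cuts[1] + 1):cuts[2]]] <- "val"
  part[perm[(cuts[2] + 1):n]] <- "test"
  stats::setNames(part, ids)
}

#' Combined multi-output mean-absolute-error loss
#'
#' The per-dimension MAE is computed over the records where the target
#' is present (missing targets are masked) and the dimensions are
#' summed.
#'
#' @param predictions,targets Numeric matrices of identical shape
#'   (records x output dimensions); `NA` targets are masked.
#' @return Scalar loss.
#' @export
combined_loss <- function(predictions, targets) {
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  stopifnot(all(dim(predictions) == dim(targets)))
  if (all(is.na(targets))) stop("no unmasked targets")
  tot <- 0
  for (d in seq_len(ncol(targets))) {
    ok <- !is.na(targets[, d])
    if (any(ok))
      tot <- tot + mean(abs(predictions[ok, d] - targets[ok, d]))
  }
  tot
}

# Gradient of combined_loss wrt predictions: sign/count per dimension.
.combined_loss_grad <- function(predictions, targets) {
  gr <- matrix(0, nrow(targets), ncol(targets))
  for (d in seq_len(ncol(targets))) {
    ok <- !is.na(targets[, d])
    if (any(ok))
      gr[ok, d] <- sign(predictions[ok, d] - targets[ok, d]) / sum(ok)
  }
  gr
}

.adamw_init <- function(params) {
  list(m = .zero_like(params), v = .zero_like(params), t = 0L)
}

.adamw_step <- function(params, grads, state, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        clip = Inf) {
  if (is.finite(clip)) {
    nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (nrm > clip) grads <- lapply(grads, function(g) g * clip / nrm)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# ---- record construction ------------------------------------------------

# A dataset for training is a list of records. For the sd variant each
# record is (molecule, solvent) with the potential target plus the
# molecule's EA as auxiliary target; for vs, one record per molecule
# with the 5-potential vector + EA. Graphs are featurized once.
.build_records <- function(data, config, registry) {
  stopifnot(all(c("id", "smiles") %in% names(data)))
  ids <- as.character(data$id)
  graphs <- lapply(data$smiles, function(s)
    .prep_graph(featurize(s, config$vocabulary)))
  names(graphs) <- ids
  pots <- paste0("E_", config$solvents)
  have <- pots %in% names(data)
  ea <- if ("ea" %in% names(data)) data$ea else rep(NA_real_, nrow(data))
  sdesc <- lapply(config$solvents, function(s)
    descriptor_vector(get_solvent(s, registry), config$descriptor_transform))
  names(sdesc) <- config$solvents
  recs <- list()
  if (config$variant == "sd") {
    for (r in seq_len(nrow(data))) {
      for (k in seq_along(config$solvents)) {
        if (!have[k]) next
        y <- data[[pots[k]]][r]
        if (is.na(y)) next
        recs[[length(recs) + 1L]] <-
          list(id = ids[r], solvent = config$solvents[k],
               sdesc = sdesc[[config$solvents[k]]],
               target = y, ea = ea[r])
      }
    }
  } else {
    for (r in seq_len(nrow(data))) {
      y <- vapply(seq_along(pots), function(k)
        if (have[k]) data[[pots[k]]][r] else NA_real_, numeric(1))
      recs[[length(recs) + 1L]] <-
        list(id = ids[r], targets = y, ea = ea[r])
    }
  }
  list(records = recs, graphs = graphs, ids = ids)
}

# Forward a set of records; returns predictions and targets matrices
# (columns: sd -> RP, EA; vs -> one per solvent then EA).
.forward_records <- function(model, recs, graphs, cache = FALSE) {
  cfg <- model$config
  nr <- length(recs)
  if (cfg$variant == "sd") {
    P <- matrix(NA_real_, nr, 2L); Tg <- matrix(NA_real_, nr, 2L)
    colnames(P) <- colnames(Tg) <- c("potential", "ea")
    fws <- if (cache) vector("list", nr)
    for (i in seq_len(nr)) {
      rc <- recs[[i]]
      fw <- .mpnn_forward(model, graphs[[rc$id]], rc$sdesc, cache = cache)
      P[i, ] <- c(fw$reduction_potential, fw$ea)
      Tg[i, ] <- c(rc$target, rc$ea)
      if (cache) fws[[i]] <- fw
    }
  } else {
    ns <- cfg$n_solvents
    P <- matrix(NA_real_, nr, ns + 1L); Tg <- matrix(NA_real_, nr, ns + 1L)
    colnames(P) <- colnames(Tg) <- c(cfg$solvents, "ea")
    fws <- if (cache) vector("list", nr)
    for (i in seq_len(nr)) {
      rc <- recs[[i]]
      fw <- .mpnn_forward(model, graphs[[rc$id]], cache = cache)
      P[i, ] <- c(fw$potentials, fw$ea)
      Tg[i, ] <- c(rc$targets, rc$ea)
      if (cache) fws[[i]] <- fw
    }
  }
  list(pred = P, target = Tg, fws = fws)
}

# One optimization pass over a batch of records; returns updated model
# and optimizer state plus the batch loss.
.train_batch <- function(model, recs, graphs, opt, control) {
  fw <- .forward_records(model, recs, graphs, cache = TRUE)
  loss <- combined_loss(fw$pred, fw$target)
  gr <- .combined_loss_grad(fw$pred, fw$target)
  grads <- .zero_like(model$params)
  cfg <- model$config
  for (i in seq_along(recs)) {
    rc <- recs[[i]]
    if (cfg$variant == "sd") {
      d_out <- list(d_ea = gr[i, 1L] + gr[i, 2L], d_solv = gr[i, 1L])
    } else {
      ns <- cfg$n_solvents
      d_out <- list(d_ea = gr[i, ns + 1L], d_pots = gr[i, seq_len(ns)])
    }
    grads <- .mpnn_backward(model, graphs[[rc$id]], fw$fws[[i]], d_out,
                            grads)
  }
  st <- .adamw_step(model$params, grads, opt, control$learning_rate,
                    control$weight_decay, clip = control$grad_clip)
  model$params <- st$params
  list(model = model, opt = st$state, loss = loss)
}

# Full training loop with best-validation checkpointing.
.train_loop <- function(model, records, graphs, train_idx, val_idx,
                        control) {
  opt <- .adamw_init(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(params = model$params, val = Inf, epoch = 0L)
  for (ep in seq_len(control$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    for (b in batches) {
      st <- .train_batch(model, records[b], graphs, opt, control)
      model <- st$model; opt <- st$opt
      if (!is.finite(st$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      ep_loss <- ep_loss + st$loss * length(b)
    }
    ep_loss <- ep_loss / length(train_idx)
    vfw <- .forward_records(model, records[val_idx], graphs)
    vloss <- combined_loss(vfw$pred, vfw$target)
    if (!is.finite(vloss))
      stop("training diverged (non-finite validation loss) at epoch ", ep)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss,
                                val_loss = vloss))
    if (vloss < best$val)
      best <- list(params = model$params, val = vloss, epoch = ep)
    if (control$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss,
                      vloss))
  }
  if (is.finite(best$val)) model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Accuracy metrics of reduction-potential predictions
#'
#' MAE and coefficient of determination R^2 = 1 - SS_res/SS_tot,
#' computed per solvent and summarized two ways: the unweighted mean of
#' the per-solvent values (the headline number) and pooled over all
#' records. R^2 is undefined (NA) for constant targets.
#'
#' @param pred,obs Numeric vectors of predictions and observations.
#' @param solvent Character vector assigning each record to a solvent.
#' @return A list of class `"redox_metrics"`.
#' @export
redox_metrics <- function(pred, obs, solvent = rep("all", length(pred))) {
  ok <- !is.na(obs) & !is.na(pred)
  pred <- pred[ok]; obs <- obs[ok]; solvent <- solvent[ok]
  if (!length(obs)) stop("no records to evaluate")
  r2 <- function(p, o) {
    sst <- sum((o - mean(o))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((o - p)^2) / sst
  }
  per <- do.call(rbind, lapply(split(seq_along(obs), solvent), function(ix)
    data.frame(solvent = solvent[ix[1]],
               mae = mean(abs(pred[ix] - obs[ix])),
               r2 = r2(pred[ix], obs[ix]), n = length(ix))))
  rownames(per) <- NULL
  structure(list(per_solvent = per,
                 mae = mean(per$mae),
                 r2 = mean(per$r2),
                 mae_pooled = mean(abs(pred - obs)),
                 r2_pooled = r2(pred, obs),
                 n = length(obs)),
            class = "redox_metrics")
}

#' @export
print.redox_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4f eV, R2 %.3f (mean over %d solvent(s), n = %d)\n",
              x$mae, x$r2, nrow(x$per_solvent), x$n))
  print(x$per_solvent, row.names = FALSE)
  invisible(x)
}
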