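#' Fit a multi-solvent reduction-potential network
#'
#' Trains the message-passing network with attention readout on a
#' molecule table and returns a fitted model object. The table has one
#' row per molecule with columns `id`, `smiles`, optionally `ea`
#' (electron affinity, eV) and one `E_<solvent>` column per solvent
#' (reduction potentials, eV) — the schema produced by
#' [gen_dataset()].
#'
#' Molecules are split into train/validation/test partitions at the
#' molecule level (all records of a molecule share one partition), the
#' summed per-dimension MAE is minimized with AdamW, and the
#' best-validation-epoch parameters are retained.
#'
#' @param data Molecule table (see above).
#' @param variant `"sd"` or `"vs"`; ignored if `config` is given.
#' @param config An [model_config()]; defaults to `model_config(variant)`.
#' @param control A [train_control()].
#' @param split Optional precomputed assignment from
#'   [split_molecules()]; by default one is drawn from
#'   `control$seed`.
#' @param exclude_solvents Character vector of solvents whose records
#'   are dropped from training and validation (the leave-one-solvent-out
#'   mechanism); `"sd"` variant only.
#' @param registry Solvent registry used for descriptor lookups.
#' @return An object of class `"redox_gnn"`.
#' @seealso [loso_protocol()], [predict.redox_gnn()]
#' @export
redox_gnn <- function(data, variant = c("sd", "vs"), config = NULL,
                      control = train_control(), split = NULL,
                      exclude_solvents = character(),
                      registry = solvent_registry()) {
  cl <- match.call()
  variant <- match.arg(variant)
  if (is.null(config)) config <- model_config(variant)
  stopifnot(inherits(config, "mpnn_config"),
            inherits(control, "train_control"))
  if (length(exclude_solvents) && config$variant != "sd")
    stop("solvent exclusion applies to the sd variant only")
  exclude_solvents <- vapply(exclude_solvents, function(s)
    get_solvent(s, registry)$name, character(1))

  built <- .build_records(data, config, registry)
  if (is.null(split))
    split <- split_molecules(built$ids, control$ratios, control$seed)
  if (!all(built$ids %in% names(split)))
    stop("split does not cover all molecule ids")

  rec_part <- vapply(built$records, function(r) unname(split[r$id]),
                     character(1))
  rec_solv <- if (config$variant == "sd")
    vapply(built$records, `[[`, character(1), "solvent")
  else rep(NA_character_, length(built$records))

  usable <- if (config$variant == "sd")
    !(rec_solv %in% exclude_solvents) else rep(TRUE, length(built$records))
  train_idx <- which(rec_part == "train" & usable)
  val_idx <- which(rec_part == "val" & usable)
  if (!length(train_idx) || !length(val_idx))
    stop("empty train or validation partition")

  set.seed(control$seed)
  model <- mpnn_init(config, seed = control$seed)
  tr <- .train_loop(model, built$records, built$graphs, train_idx,
                    val_idx, control)

  fit <- structure(
    list(model = tr$model, config = config, control = control,
         split = split, history = tr$history,
         best_epoch = tr$best_epoch, data = data,
         records = built$records, graphs = built$graphs,
         rec_part = rec_part, rec_solv = rec_solv,
         exclude_solvents = exclude_solvents,
         registry = registry, call = cl),
    class = "redox_gnn")
  fit$test_metrics <- tryCatch(evaluate(fit, partition = "test"),
                               error = function(e) NULL)
  fit
}

#' Evaluate a fitted model on a data partition
#'
#' Computes per-solvent MAE and R^2 of the reduction-potential
#' predictions on the records of one partition (default `"test"`).
#'
#' @param fit A fitted [redox_gnn()] model.
#' @param partition `"train"`, `"val"` or `"test"`.
#' @param solvents Optional solvent names to restrict to.
#' @return A [redox_metrics()] object.
#' @export
evaluate <- function(fit, partition = "test", solvents = NULL) {
  stopifnot(inherits(fit, "redox_gnn"))
  idx <- which(fit$rec_part %in% partition)
  if (!is.null(solvents)) {
    solvents <- vapply(solvents, function(s)
      get_solvent(s, fit$registry)$name, character(1))
    if (fit$config$variant == "sd")
      idx <- idx[fit$rec_solv[idx] %in% solvents]
  }
  if (!length(idx)) stop("no records in partition")
  fw <- .forward_records(fit$model, fit$records[idx], fit$graphs)
  if (fit$config$variant == "sd") {
    redox_metrics(fw$pred[, 1L], fw$target[, 1L], fit$rec_solv[idx])
  } else {
    ns <- fit$config$n_solvents
    sel <- if (is.null(solvents)) seq_len(ns)
           else which(fit$config$solvents %in% solvents)
    pred <- as.vector(fw$pred[, sel, drop = FALSE])
    obs <- as.vector(fw$target[, sel, drop = FALSE])
    sv <- rep(fit$config$solvents[sel], each = length(idx))
    redox_metrics(pred, obs, sv)
  }
}

#' Leave-one-solvent-out generalization protocol
#'
#' Retrains the solvent-conditioned (`"sd"`) model with every record of
#' one solvent withheld from training and validation, then evaluates
#' only the withheld-solvent records of the test molecules — the test
#' of zero-shot generalization to an unseen solvent. The returned
#' audit proves the training stream contained no withheld-solvent
#' record.
#'
#' @param data Molecule table (see [redox_gnn()]).
#' @param withheld_solvent Solvent name to withhold.
#' @param config,control,registry As in [redox_gnn()].
#' @return A list of class `"loso_result"` with elements `fit`,
#'   `metrics` (on the withheld solvent), `withheld`, and `audit`
#'   (record counts by solvent actually used in training).
#' @export
loso_protocol <- function(data, withheld_solvent, config = NULL,
                          control = train_control(),
                          registry = solvent_registry()) {
  if (is.null(config)) config <- model_config("sd")
  stopifnot(config$variant == "sd")
  withheld <- get_solvent(withheld_solvent, registry)$name
  if (!withheld %in% config$solvents)
    stop("withheld solvent '", withheld, "' is not in the dataset solvents")
  if (!paste0("E_", withheld) %in% names(data))
    stop("dataset has no records for solvent '", withheld, "'")
  fit <- redox_gnn(data, config = config, control = control,
                   exclude_solvents = withheld, registry = registry)
  train_solvents <- fit$rec_solv[fit$rec_part == "train" &
                                   !(fit$rec_solv %in% withheld)]
  audit <- table(factor(train_solvents, levels = config$solvents))
  metrics <- evaluate(fit, partition = "test", solvents = withheld)
  structure(list(fit = fit, metrics = metrics, withheld = withheld,
                 audit = audit),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("leave-one-solvent-out: withheld", x$withheld, "\n")
  print(x$metrics)
  invisible(x)
}

# ---- S3 methods ---------------------------------------------------------

#' @export
print.redox_gnn <- function(x, ...) {
  cat("redox_gnn fit (GNN-", toupper(x$config$variant), ")\n", sep = "")
  cat("  molecules:", length(unique(names(x$split))),
      " records:", length(x$records), "\n")
  if (nrow(x$history))
    cat(sprintf("  best validation loss %.4f at epoch %d/%d\n",
                min(x$history$val_loss), x$best_epoch,
                max(x$history$epoch)))
  if (length(x$exclude_solvents))
    cat("  solvents withheld from training:",
        paste(x$exclude_solvents, collapse = ", "), "\n")
  if (!is.null(x$test_metrics))
    cat(sprintf("  test MAE %.4f eV, R2 %.3f\n", x$test_metrics$mae,
                x$test_metrics$r2))
  invisible(x)
}

#' @export
summary.redox_gnn <- function(object, ...) {
  print(object)
  cat("\nper-solvent test metrics:\n")
  if (!is.null(object$test_metrics))
    print(object$test_metrics$per_solvent, row.names = FALSE)
  invisible(object)
}

#' Predict reduction potentials for new molecules
#'
#' @param object A fitted [redox_gnn()] model.
#' @param newdata Character vector of SMILES, or a data.frame with a
#'   `smiles` column.
#' @param solvent Solvent name(s) (sd variant; recycled across
#'   molecules).
#' @param ... Unused.
#' @return A data.frame: for `"sd"`, columns `smiles`, `solvent`,
#'   `ea_component`, `solvent_component`, `reduction_potential`; for
#'   `"vs"`, `smiles`, `ea_component` and one column per solvent.
#' @export
predict.redox_gnn <- function(object, newdata, solvent = NULL, ...) {
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  graphs <- lapply(smiles, featurize, vocabulary = object$config$vocabulary)
  if (object$config$variant == "sd") {
    if (is.null(solvent)) stop("sd variant requires `solvent`")
    solvent <- rep_len(solvent, length(smiles))
    rows <- lapply(seq_along(smiles), function(i) {
      p <- forward_sd(object$model, graphs[[i]], solvent[i],
                      object$registry)
      data.frame(smiles = smiles[i], solvent = solvent[i],
                 ea_component = p$ea_component,
                 solvent_component = p$solvent_component,
                 reduction_potential = p$reduction_potential,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    rows <- lapply(seq_along(smiles), function(i) {
      p <- forward_vs(object$model, graphs[[i]])
      out <- data.frame(smiles = smiles[i], ea_component = p$ea_component,
                        stringsAsFactors = FALSE)
      for (s in names(p$potentials)) out[[s]] <- unname(p$potentials[s])
      out
    })
    do.call(rbind, rows)
  }
}

#' @export
residuals.redox_gnn <- function(object, partition = c("test", "train",
                                                      "val"), ...) {
  partition <- match.arg(partition)
  idx <- which(object$rec_part == partition)
  fw <- .forward_records(object$model, object$records[idx],
                         object$graphs)
  drop(fw$pred[, 1L] - fw$target[, 1L])
}

#' @export
coef.redox_gnn <- function(object, ...) {
  unlist(object$model$params)
}

#' @export
plot.redox_gnn <- function(x, ...) {
  if (!nrow(x$history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "combined MAE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save and load a fitted model checkpoint
#'
#' The checkpoint is a directory holding the configuration, weights and
#' training metadata as JSON/CSV text; loading validates configuration
#' compatibility.
#'
#' @param fit A `redox_gnn` object.
#' @param dir Checkpoint directory.
#' @return `save_redox_gnn()` returns `dir` invisibly;
#'   `load_redox_gnn()` returns a `redox_gnn` usable for prediction.
#' @export
save_redox_gnn <- function(fit, dir) {
  stopifnot(inherits(fit, "redox_gnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  weights <- lapply(fit$model$params, function(w)
    if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
    else list(dim = length(w), data = as.vector(w)))
  jsonlite::write_json(weights, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = FALSE)
  meta <- list(seed = fit$control$seed, best_epoch = fit$best_epoch,
               n_molecules = length(unique(names(fit$split))),
               data_hash = sum(utf8ToInt(paste(fit$data$smiles,
                                               collapse = ""))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_redox_gnn
#' @export
load_redox_gnn <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(variant = cfgl$variant,
                      n_message_iterations = cfgl$n_message_iterations,
                      node_dim = cfgl$node_dim, edge_dim = cfgl$edge_dim,
                      graph_dim = cfgl$graph_dim,
                      n_attention_heads = cfgl$n_attention_heads,
                      head_hidden = cfgl$head_hidden,
                      solvents = cfgl$solvents,
                      descriptor_transform = cfgl$descriptor_transform,
                      vocabulary = cfgl$vocabulary)
  ws <- jsonlite::read_json(file.path(dir, "weights.json"),
                            simplifyVector = TRUE)
  model <- mpnn_init(cfg, seed = 0L)
  for (nm in names(model$params)) {
    if (is.null(ws[[nm]]))
      stop("checkpoint incompatible with configuration: missing ", nm)
    w <- ws[[nm]]
    model$params[[nm]] <- if (is.matrix(model$params[[nm]]))
      matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  history <- tryCatch(utils::read.csv(file.path(dir, "history.csv")),
                      error = function(e) data.frame())
  structure(list(model = model, config = cfg,
                 control = train_control(seed = meta$seed),
                 split = character(), history = history,
                 best_epoch = meta$best_epoch, data = NULL,
                 records = list(), graphs = list(),
                 rec_part = character(), rec_solv = character(),
                 exclude_solvents = character(),
                 registry = solvent_registry(), call = NULL,
                 test_metrics = NULL),
            class = "redox_gnn")
}
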