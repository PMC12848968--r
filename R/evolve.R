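#' Target potential window for inverse design
#'
#' An absolute-potential interval \[lo, hi\] with a sigmoid steepness.
#' The window objective is a linear combination of a sigmoid and a
#' 1-sigmoid, \deqn{f(x) = \sigma(k(x - lo)) - \sigma(k(x - hi)),}
#' which returns ~1 deep inside the window and ~0 far outside.
#'
#' @param lo,hi Window edges, volts on the absolute scale (`lo < hi`).
#' @param steepness Sigmoid steepness k in 1/V (default 50, so even a
#'   0.25 V window scores ~1 at its midpoint).
#' @return A list of class `"target_window"`.
#' @export
target_window <- function(lo, hi, steepness = 50) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi, steepness > 0)
  structure(list(lo = lo, hi = hi, steepness = steepness),
            class = "target_window")
}

#' Windowed sigmoid objective score
#'
#' @param x Predicted potential(s), volts (absolute scale).
#' @param window A [target_window()].
#' @return Score(s) in \[0, 1\].
#' @examples
#' w <- target_window(4.0, 5.0)
#' window_score(4.5, w)   # ~1
#' window_score(2.0, w)   # ~0
#' @export
window_score <- function(x, window) {
  stopifnot(inherits(window, "target_window"))
  k <- window$steepness
  stats::plogis(k * (x - window$lo)) - stats::plogis(k * (x - window$hi))
}

#' Application potential-window presets
#'
#' Experimentally motivated target windows for four battery-related
#' applications, quoted against their usual reference electrodes:
#' redox matching of the conducting polymers PEDOT
#' (-0.90..-0.19 V vs Fc0/Fc+, acetonitrile) and PPT
#' (-2.24..-1.99 V vs Fc0/Fc+, acetonitrile), lithium-ion electrolyte
#' additives (2.5..3.5 V vs Li/Li+, DMSO), and redox-flow-battery
#' anolytes (-0.4..0.2 V vs SHE, water). `window_to_absolute()`
#' converts a preset to the absolute scale using the electrode
#' registry offsets (the ferrocene and lithium offsets are explicit
#' configuration, see [reference_electrode()]).
#'
#' @return A named list of presets, each with `lo`, `hi`, `ref`,
#'   `solvent`.
#' @export
application_windows <- function() {
  list(
    pedot = list(lo = -0.90, hi = -0.19, ref = "Fc",
                 solvent = "acetonitrile"),
    ppt = list(lo = -2.24, hi = -1.99, ref = "Fc",
               solvent = "acetonitrile"),
    li_additive = list(lo = 2.5, hi = 3.5, ref = "Li",
                       solvent = "dimethylsulfoxide"),
    rfb_anolyte = list(lo = -0.4, hi = 0.2, ref = "SHE",
                       solvent = "water")
  )
}

#' @rdname application_windows
#' @param preset A preset from [application_windows()] (or a list with
#'   `lo`, `hi`, `ref`).
#' @param steepness Sigmoid steepness for the resulting window.
#' @export
window_to_absolute <- function(preset, steepness = 50) {
  target_window(to_absolute(preset$lo, preset$ref),
                to_absolute(preset$hi, preset$ref), steepness)
}

#' Synthetic-accessibility score
#'
#' Fragment-contribution plus complexity-penalty synthetic
#' accessibility, ~1 (easy to make) to ~10 (hard), computed by the
#' reference implementation (bundled script run through the local
#' Python/RDKit; calls are batched, one process per call).
#'
#' @param smiles Character vector of SMILES.
#' @param python Python executable.
#' @return Numeric vector of scores (`NA` for unparsable input).
#' @export
sa_score <- function(smiles, python = getOption("redoxgnn.python",
                                                Sys.which("python"))) {
  if (!nzchar(python)) stop("no python executable found for SA scoring")
  script <- system.file("python", "sa_score.py", package = "redoxgnn")
  if (!nzchar(script))
    script <- file.path("inst", "python", "sa_score.py")
  inp <- tempfile(); on.exit(unlink(inp))
  writeLines(smiles, inp)
  out <- suppressWarnings(system2(python, shQuote(script),
                                  stdin = inp, stdout = TRUE,
                                  stderr = FALSE))
  if (length(out) != length(smiles))
    stop("SA scoring failed (", length(out), " scores for ",
         length(smiles), " inputs)")
  suppressWarnings(as.numeric(out))
}

#' Synthetic-accessibility gate
#'
#' @param g A `mol_graph`, `edit_mol` or SMILES string.
#' @param threshold Maximal admissible score.
#' @param ... Passed to [sa_score()].
#' @return List with `pass` and `score`.
#' @export
sa_gate <- function(g, threshold = 4.5, ...) {
  smi <- if (inherits(g, "mol_graph")) g$smiles
         else if (inherits(g, "edit_mol")) edit_mol_to_smiles(g)
         else g
  sc <- sa_score(smi, ...)
  if (is.na(sc)) return(list(pass = FALSE, score = NA_real_,
                             reason = "featurization failure"))
  list(pass = sc <= threshold, score = sc)
}

#' Evolution configuration
#'
#' Constraints and loop parameters of the evolutionary search: at most
#' 15 heavy atoms and elements from \{C, N, O, F, S, Cl, Br\} by
#' default, a synthetic-accessibility ceiling, and a (mu + lambda)
#' elitist loop with mutation-only variation.
#'
#' @param max_heavy_atoms Maximum heavy-atom count.
#' @param allowed_elements Allowed element symbols.
#' @param sa_threshold Synthetic-accessibility ceiling.
#' @param population_size Survivors per generation (mu); also the
#'   number of offspring attempted (lambda).
#' @param max_generations Generation cap.
#' @param time_limit Wall-clock cap in seconds (`Inf` disables).
#' @param seed RNG seed.
#' @return A list of class `"evolution_config"`.
#' @export
evolution_config <- function(max_heavy_atoms = 15L,
                             allowed_elements = c("C", "N", "O", "F",
                                                  "S", "Cl", "Br"),
                             sa_threshold = 4.5,
                             population_size = 20L,
                             max_generations = 50L,
                             time_limit = Inf, seed = 1L) {
  stopifnot(max_heavy_atoms >= 1, length(allowed_elements) >= 1,
            population_size >= 1, max_generations >= 1)
  structure(list(max_heavy_atoms = as.integer(max_heavy_atoms),
                 allowed_elements = allowed_elements,
                 sa_threshold = sa_threshold,
                 population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 time_limit = time_limit, seed = as.integer(seed)),
            class = "evolution_config")
}

.mutation_actions <- c("add_atom", "remove_atom", "change_bond",
                       "substitute_atom", "move_group")

#' Mutate a molecular graph
#'
#' Applies one of the predefined graph edits — adding or removing an
#' atom, changing a bond order, substituting an atom type, or moving a
#' terminal group — and returns either a chemically valid mutated
#' molecule or a rejection with a reason (rejection is a return state,
#' not an error).
#'
#' @param mol An [edit_mol()] (or SMILES string).
#' @param action One of `"add_atom"`, `"remove_atom"`,
#'   `"change_bond"`, `"substitute_atom"`, `"move_group"`.
#' @param cfg An [evolution_config()] supplying the constraints.
#' @return List with `accepted` (logical) and either `mol` (an
#'   `edit_mol`) or `reason`.
#' @export
mutate_mol <- function(mol, action = sample(.mutation_actions, 1L),
                       cfg = evolution_config()) {
  if (is.character(mol)) mol <- smiles_to_edit_mol(mol)
  stopifnot(inherits(mol, "edit_mol"))
  action <- match.arg(action, .mutation_actions)
  n <- length(mol$elements)
  rej <- function(reason) list(accepted = FALSE, reason = reason)
  out <- switch(action,
    add_atom = {
      if (n >= cfg$max_heavy_atoms) return(rej("size"))
      fv <- .free_valence(mol)
      host <- which(fv >= 1)
      if (!length(host)) return(rej("no free valence"))
      a <- if (length(host) == 1L) host else sample(host, 1L)
      el <- sample(cfg$allowed_elements, 1L)
      mol$elements <- c(mol$elements, el)
      mol$bonds <- rbind(mol$bonds,
                         data.frame(i = a, j = n + 1L, order = 1L))
      mol
    },
    remove_atom = {
      if (n <= 1L) return(rej("would empty graph"))
      cand <- which(vapply(seq_len(n), function(a) {
        keep <- setdiff(seq_len(n), a)
        b <- mol$bonds[mol$bonds$i != a & mol$bonds$j != a, , drop = FALSE]
        remap <- match(seq_len(n), keep)
        m2 <- edit_mol(mol$elements[keep],
                       data.frame(i = remap[b$i], j = remap[b$j],
                                  order = b$order))
        .mol_connected(m2)
      }, logical(1)))
      if (!length(cand)) return(rej("no removable atom"))
      a <- if (length(cand) == 1L) cand else sample(cand, 1L)
      keep <- setdiff(seq_len(n), a)
      b <- mol$bonds[mol$bonds$i != a & mol$bonds$j != a, , drop = FALSE]
      remap <- match(seq_len(n), keep)
      edit_mol(mol$elements[keep],
               data.frame(i = remap[b$i], j = remap[b$j],
                          order = b$order))
    },
    change_bond = {
      if (nrow(mol$bonds) == 0L) return(rej("no bonds"))
      k <- sample(nrow(mol$bonds), 1L)
      fv <- .free_valence(mol)
      cur <- mol$bonds$order[k]
      slack <- min(fv[mol$bonds$i[k]], fv[mol$bonds$j[k]])
      opts <- setdiff(seq_len(min(3L, cur + slack)), cur)
      if (!length(opts)) return(rej("no admissible bond order"))
      mol$bonds$order[k] <- if (length(opts) == 1L) opts
                            else sample(opts, 1L)
      mol
    },
    substitute_atom = {
      used <- .used_valence(mol)
      pick <- expand.grid(a = seq_len(n), el = cfg$allowed_elements,
                          stringsAsFactors = FALSE)
      pick <- pick[pick$el != mol$elements[pick$a] &
                     .typical_valence[pick$el] >= used[pick$a], ,
                   drop = FALSE]
      if (!nrow(pick)) return(rej("no admissible substitution"))
      k <- sample(nrow(pick), 1L)
      mol$elements[pick$a[k]] <- pick$el[k]
      mol
    },
    move_group = {
      if (n < 3L) return(rej("too small to move a group"))
      deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
      leaves <- which(deg == 1L)
      if (!length(leaves)) return(rej("no terminal group"))
      a <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
      k <- which(mol$bonds$i == a | mol$bonds$j == a)
      ord <- mol$bonds$order[k]
      old <- setdiff(c(mol$bonds$i[k], mol$bonds$j[k]), a)
      m2 <- mol
      m2$bonds <- m2$bonds[-k, , drop = FALSE]
      fv <- .free_valence(m2)
      fv[a] <- -1  # cannot reattach to itself
      hosts <- setdiff(which(fv >= ord), old)
      if (!length(hosts)) return(rej("no reattachment site"))
      b <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
      m2$bonds <- rbind(m2$bonds, data.frame(i = b, j = a, order = ord))
      if (!.mol_connected(m2)) return(rej("would disconnect"))
      m2
    })
  if (is.list(out) && !is.null(out$accepted)) return(out)
  v <- .mol_valid(out, cfg$allowed_elements, cfg$max_heavy_atoms)
  if (!isTRUE(v)) return(rej(v))
  list(accepted = TRUE, mol = out)
}

#' Prediction interface used by the inverse-design objective
#'
#' Any predictor of reduction potentials can drive the evolutionary
#' search; methods exist for fitted [redox_gnn()] models, raw
#' `mpnn_model`s, and [synthetic_truth()] oracles.
#'
#' @param object Predictor.
#' @param g A `mol_graph`.
#' @param solvent Solvent name or [solvent_spec()].
#' @param ... Method-specific arguments.
#' @return Predicted reduction potential (eV).
#' @export
predict_potential <- function(object, g, solvent, ...) {
  UseMethod("predict_potential")
}

#' @export
predict_potential.mpnn_model <- function(object, g, solvent, ...) {
  if (object$config$variant == "sd")
    forward_sd(object, g, solvent, ...)$reduction_potential
  else {
    s <- get_solvent(solvent)$name
    if (!s %in% object$config$solvents)
      stop("vs model has no output for solvent '", s, "'")
    unname(forward_vs(object, g)$potentials[s])
  }
}

#' @export
predict_potential.redox_gnn <- function(object, g, solvent, ...) {
  predict_potential(object$model, g, solvent,
                    registry = object$registry)
}

#' @export
predict_potential.synthetic_truth <- function(object, g, solvent, ...) {
  synth_potential(g, solvent, object)$e_red
}

#' Ensemble window objective
#'
#' Scores a molecule by the mean windowed-sigmoid score of the
#' predictions of all ensemble members, and accepts it only if every
#' member's prediction lies inside \[lo, hi\] — the implicit
#' uncertainty treatment of the deep ensemble.
#'
#' @param g A `mol_graph`.
#' @param models Non-empty list of predictors (see
#'   [predict_potential()]).
#' @param solvent Solvent of the target application.
#' @param window A [target_window()].
#' @return List with `score`, `accept`, `predictions` (and `reason` on
#'   failure).
#' @export
ensemble_objective <- function(g, models, solvent, window) {
  if (!length(models)) stop("ensemble must contain at least one model")
  preds <- tryCatch(
    vapply(models, predict_potential, numeric(1), g = g,
           solvent = solvent),
    error = function(e) NULL)
  if (is.null(preds) || !all(is.finite(preds)))
    return(list(score = 0, accept = FALSE, predictions = preds,
                reason = "model failure"))
  list(score = mean(window_score(preds, window)),
       accept = all(preds >= window$lo & preds <= window$hi),
       predictions = preds)
}

#' Evolutionary inverse design of redox-active molecules
#'
#' (mu + lambda) elitist evolutionary search over molecular graphs:
#' each generation mutates randomly chosen parents with random graph
#' actions, keeps chemically valid offspring within the element and
#' size constraints, gates them on synthetic accessibility, scores
#' them with `objective`, and retains the top `population_size`
#' candidates. Accepted candidates (objective `accept = TRUE`) are
#' archived and returned ranked, de-duplicated by canonical SMILES.
#' Deterministic for a fixed seed.
#'
#' @param seeds Character vector of seed SMILES.
#' @param cfg An [evolution_config()].
#' @param objective Function `(smiles, mol_graph) -> list(score,
#'   accept, ...)`, e.g. a closure over [ensemble_objective()].
#' @param use_sa_gate Disable to skip synthetic-accessibility gating
#'   (e.g. where no Python is available).
#' @return A data.frame of class `"evolve_result"`: the accepted
#'   candidates ranked by score, with per-generation statistics in
#'   attribute `"log"`.
#' @export
evolve_loop <- function(seeds, cfg = evolution_config(), objective,
                        use_sa_gate = TRUE) {
  stopifnot(is.character(seeds), length(seeds) >= 1L)
  set.seed(cfg$seed)
  t_start <- Sys.time()

  eval_one <- function(smi) {
    g <- tryCatch(featurize(smi), error = function(e) NULL)
    if (is.null(g)) return(NULL)
    ob <- objective(smi, g)
    list(smiles = smi, score = ob$score, accept = isTRUE(ob$accept),
         predictions = ob$predictions)
  }

  pop <- list()
  for (s in seeds) {
    mol <- tryCatch(smiles_to_edit_mol(s), error = function(e) NULL)
    if (is.null(mol)) next
    v <- .mol_valid(mol, cfg$allowed_elements, cfg$max_heavy_atoms)
    if (!isTRUE(v)) next
    smi <- edit_mol_to_smiles(mol)
    ev <- eval_one(smi)
    if (!is.null(ev)) { ev$generation <- 0L; ev$parent <- NA_character_
      pop[[smi]] <- ev }
  }
  if (!length(pop)) stop("no valid seed molecules")
  if (use_sa_gate) {
    sas <- sa_score(names(pop))
    for (i in seq_along(pop)) pop[[i]]$sa <- sas[i]
  } else for (i in seq_along(pop)) pop[[i]]$sa <- NA_real_

  archive <- list()
  for (cand in pop)
    if (cand$accept && (!use_sa_gate || cand$sa <= cfg$sa_threshold))
      archive[[cand$smiles]] <- cand

  log <- data.frame()
  for (gen in seq_len(cfg$max_generations)) {
    if (as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
        cfg$time_limit) break
    parents <- names(pop)
    children <- list()
    for (k in seq_len(cfg$population_size)) {
      psmi <- if (length(parents) == 1L) parents
              else sample(parents, 1L)
      mol <- tryCatch(smiles_to_edit_mol(psmi), error = function(e) NULL)
      if (is.null(mol)) next
      mu <- mutate_mol(mol, sample(.mutation_actions, 1L), cfg)
      if (!mu$accepted) next
      smi <- tryCatch(edit_mol_to_smiles(mu$mol), error = function(e) NULL)
      if (is.null(smi) || smi %in% names(pop) ||
          smi %in% names(children)) next
      ev <- eval_one(smi)
      if (is.null(ev)) next
      ev$generation <- gen; ev$parent <- psmi
      children[[smi]] <- ev
    }
    if (length(children)) {
      if (use_sa_gate) {
        sas <- sa_score(names(children))
        keep <- !is.na(sas) & sas <= cfg$sa_threshold
        for (i in seq_along(children)) children[[i]]$sa <- sas[i]
        children <- children[keep]
      } else for (i in seq_along(children)) children[[i]]$sa <- NA_real_
    }
    for (cand in children)
      if (cand$accept) archive[[cand$smiles]] <- cand
    pool <- c(pop, children)
    scores <- vapply(pool, `[[`, numeric(1), "score")
    pop <- pool[order(-scores)[seq_len(min(cfg$population_size,
                                           length(pool)))]]
    log <- rbind(log, data.frame(
      generation = gen, n_offspring = length(children),
      best_score = max(scores), mean_score = mean(scores),
      n_accepted = length(archive)))
  }

  to_df <- function(lst) {
    if (!length(lst))
      return(data.frame(smiles = character(), score = numeric(),
                        sa_score = numeric(), generation = integer(),
                        parent = character()))
    do.call(rbind, lapply(lst, function(c)
      data.frame(smiles = c$smiles, score = c$score, sa_score = c$sa,
                 generation = c$generation, parent = c$parent,
                 stringsAsFactors = FALSE)))
  }
  out <- to_df(archive)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- log
  attr(out, "population") <- to_df(pop)
  class(out) <- c("evolve_result", class(out))
  out
}
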