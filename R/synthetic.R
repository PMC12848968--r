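#' Synthetic ground truth for reduction potentials
#'
#' A known, smooth ground-truth function standing in for DFT-computed
#' electron affinities and reduction potentials, so the whole toolkit
#' can be exercised without any quantum chemistry. The electron
#' affinity is a linear function of size-normalized composition
#' features of the molecule; the solvent dependence follows a
#' Born-style reaction-field term in the dielectric constant plus a
#' smaller electronic-polarizability term in the refractive index:
#' \deqn{E_{red} = EA(g) + w_s \, q(g) (1 - 1/\varepsilon)
#'   + w_n (n^2-1)/(n^2+2) + \mathcal{N}(0, \sigma^2)}
#' with \eqn{q(g)} the normalized heteroatom count
#' \eqn{(1 + n_{het})/(1 + n_{heavy})}. Because the truth depends on
#' the solvent only through \eqn{(\varepsilon, n)}, zero-shot
#' generalization to an unseen solvent is genuinely learnable from the
#' two descriptors.
#'
#' @param ea_weights Named coefficient vector (eV) over the molecular
#'   composition features; see Details. `NULL` uses the defaults.
#' @param solv_weight Scale of the dielectric reaction-field term (eV).
#' @param polz_weight Scale of the refractive-index term (eV).
#' @param noise_sd Homoscedastic Gaussian noise (eV).
#' @param seed RNG seed used when generating noisy datasets.
#' @details The composition features are: an intercept, the fraction of
#'   heavy atoms of each element among N, O, F, S, Cl, Br (carbon is
#'   the reference), the aromatic-atom fraction, and the ring-atom
#'   fraction. Fractions (not raw counts) keep the target intensive,
#'   like a real potential.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(ea_weights = NULL, solv_weight = 1.5,
                            polz_weight = 0.5, noise_sd = 0.05,
                            seed = 1L) {
  if (is.null(ea_weights))
    ea_weights <- c(intercept = 1.2, N = 0.45, O = 0.85, F = 0.6,
                    S = 0.3, Cl = 0.5, Br = 0.4,
                    aromatic = 0.6, ring = -0.25)
  stopifnot(noise_sd >= 0, is.finite(solv_weight), is.finite(polz_weight))
  structure(list(ea_weights = ea_weights, solv_weight = solv_weight,
                 polz_weight = polz_weight, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

.truth_features <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- g$n_heavy
  el <- g$nodes$element
  f <- c(intercept = 1,
         N = mean(el == "N"), O = mean(el == "O"), F = mean(el == "F"),
         S = mean(el == "S"), Cl = mean(el == "Cl"),
         Br = mean(el == "Br"),
         aromatic = mean(g$nodes$aromatic),
         ring = mean(g$nodes$in_ring))
  f
}

.truth_q <- function(g) {
  (1 + sum(g$nodes$element != "C")) / (1 + g$n_heavy)
}

#' Evaluate the synthetic ground truth for one molecule and solvent
#'
#' @param g A [featurize()]d `mol_graph` (or SMILES string).
#' @param solvent A [solvent_spec()] or registered name.
#' @param truth A [synthetic_truth()].
#' @param noise If `TRUE`, add Gaussian noise of sd `truth$noise_sd`
#'   from the current RNG stream.
#' @return List with `ea` and `e_red` (eV).
#' @export
synth_potential <- function(g, solvent, truth = synthetic_truth(),
                            noise = FALSE) {
  if (is.character(g)) g <- featurize(g)
  s <- get_solvent(solvent)
  f <- .truth_features(g)
  w <- truth$ea_weights[names(f)]
  ea <- sum(w * f)
  e_red <- ea +
    truth$solv_weight * .truth_q(g) * (1 - 1 / s$epsilon) +
    truth$polz_weight * (s$refractive_index^2 - 1) /
      (s$refractive_index^2 + 2)
  if (noise && truth$noise_sd > 0)
    e_red <- e_red + stats::rnorm(1, 0, truth$noise_sd)
  list(ea = ea, e_red = e_red)
}

.element_weights <- c(C = 8, N = 2, O = 2, F = 1, S = 1, Cl = 1, Br = 1)

.gen_one_molecule <- function(max_heavy, elements) {
  w <- .element_weights[elements]
  w[is.na(w)] <- 1
  n <- sample(2:max_heavy, 1L)
  pick <- function() sample(elements, 1L, prob = w)
  mol <- edit_mol(pick())
  while (length(mol$elements) < n) {
    fv <- .free_valence(mol)
    host <- which(fv >= 1)
    if (!length(host)) break
    a <- if (length(host) == 1L) host else sample(host, 1L)
    el <- pick()
    mol$elements <- c(mol$elements, el)
    mol$bonds <- rbind(mol$bonds,
                       data.frame(i = a, j = length(mol$elements),
                                  order = 1L))
  }
  # optional ring closure
  if (length(mol$elements) >= 4 && stats::runif(1) < 0.5) {
    fv <- .free_valence(mol)
    adj <- paste(pmin(mol$bonds$i, mol$bonds$j),
                 pmax(mol$bonds$i, mol$bonds$j))
    cand <- which(fv >= 1)
    if (length(cand) >= 2) {
      pr <- t(utils::combn(cand, 2))
      ok <- !(paste(pr[, 1], pr[, 2]) %in% adj)
      pr <- pr[ok, , drop = FALSE]
      if (nrow(pr)) {
        k <- sample(nrow(pr), 1L)
        mol$bonds <- rbind(mol$bonds,
                           data.frame(i = pr[k, 1], j = pr[k, 2],
                                      order = 1L))
      }
    }
  }
  # random unsaturation where valence allows
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      if (stats::runif(1) < 0.3) {
        fv <- .free_valence(mol)
        if (fv[mol$bonds$i[k]] >= 1 && fv[mol$bonds$j[k]] >= 1)
          mol$bonds$order[k] <- mol$bonds$order[k] + 1L
      }
    }
  }
  mol
}

#' Generate random valid molecules
#'
#' Assembles random connected molecular graphs (random attachment
#' trees with optional ring closures and unsaturation) under a typical
#' valence model, and returns their unique canonical SMILES.
#' Deterministic for a fixed seed.
#'
#' @param n Number of unique molecules.
#' @param max_heavy Maximum heavy-atom count per molecule.
#' @param elements Allowed element symbols.
#' @param seed RNG seed.
#' @return Character vector of `n` canonical SMILES.
#' @export
gen_molecules <- function(n, max_heavy = 9L,
                          elements = c("C", "N", "O", "F", "S", "Cl", "Br"),
                          seed = 1L) {
  stopifnot(n >= 1, max_heavy >= 2)
  set.seed(seed)
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("could not generate ", n, " unique molecules within ",
           attempts, " attempts; constraint space too small")
    mol <- .gen_one_molecule(max_heavy, elements)
    smi <- tryCatch(edit_mol_to_smiles(mol), error = function(e) NA)
    if (is.na(smi) || smi %in% out) next
    g <- tryCatch(featurize(smi), error = function(e) NULL)
    if (is.null(g)) next
    out <- c(out, smi)
  }
  out
}

#' Generate a synthetic molecule table with known ground truth
#'
#' Produces the exact table schema the fitting functions expect: one
#' row per molecule with columns `id`, `smiles`, `ea`, and one
#' `E_<solvent>` column per solvent, evaluated from a
#' [synthetic_truth()] with Gaussian noise.
#'
#' @param n_mol Number of molecules.
#' @param solvents List of [solvent_spec()]s or registered names
#'   (default: the five training solvents).
#' @param truth A [synthetic_truth()] (its `seed` drives all
#'   randomness).
#' @param max_heavy,elements Passed to [gen_molecules()].
#' @return A data.frame; the truth object is attached as attribute
#'   `"truth"` for parameter-recovery checks.
#' @export
gen_dataset <- function(n_mol,
                        solvents = c("acetonitrile", "water",
                                     "tetrahydrofuran",
                                     "dimethylsulfoxide",
                                     "dimethylformamide"),
                        truth = synthetic_truth(),
                        max_heavy = 9L,
                        elements = c("C", "N", "O", "F", "S", "Cl", "Br")) {
  stopifnot(length(solvents) >= 2)
  specs <- lapply(solvents, get_solvent)
  smiles <- gen_molecules(n_mol, max_heavy, elements, seed = truth$seed)
  set.seed(truth$seed + 1L)
  rows <- lapply(seq_along(smiles), function(i) {
    g <- featurize(smiles[i])
    vals <- vapply(specs, function(s)
      synth_potential(g, s, truth, noise = TRUE)$e_red, numeric(1))
    ea <- synth_potential(g, specs[[1]], truth)$ea
    out <- data.frame(id = sprintf("mol%04d", i), smiles = smiles[i],
                      ea = ea, stringsAsFactors = FALSE)
    for (k in seq_along(specs)) out[[paste0("E_", specs[[k]]$name)]] <- vals[k]
    out
  })
  tab <- do.call(rbind, rows)
  attr(tab, "truth") <- truth
  tab
}

#' A sixth, synthetic solvent for leave-one-solvent-out tests
#'
#' Descriptors lie inside the envelope of the five training solvents,
#' so generalization to it is an interpolation task.
#'
#' @return A [solvent_spec()].
#' @export
synthetic_solvent <- function() {
  solvent_spec("synthsolv", epsilon = 25, refractive_index = 1.40)
}

#' Curation fixture records with known filter outcomes
#'
#' Builds species records engineered so that each of the four curation
#' filters (bond-length change, spin contamination, imaginary
#' frequency, bulk-electrostatics range) trips exactly once, plus
#' clean records. The expected outcome is stored in the
#' `expected_outcome` field of each record.
#'
#' @param seed RNG seed (jitters the clean geometries).
#' @param n_clean Number of clean records (default 6, for 10 records
#'   total).
#' @return List of species records (see [species_record()]).
#' @export
gen_curation_fixtures <- function(seed = 1L, n_clean = 6L) {
  set.seed(seed)
  base_geom <- function(nat) {
    cbind(x = seq_len(nat) * 1.0, y = rep(0, nat), z = rep(0, nat))
  }
  mk <- function(id, stretch = 1, s_squared = 0.75, mult = 2L,
                 freqs = c(100, 250, 800), bulk = -1.5,
                 expected = "kept") {
    nat <- 4L
    parent <- base_geom(nat)
    reduced <- parent
    # jitter all bonds a little, then stretch the first bond by `stretch`
    reduced[, "x"] <- reduced[, "x"] +
      cumsum(c(0, stats::runif(nat - 1, -0.02, 0.02)))
    reduced[2:nat, "x"] <- reduced[2:nat, "x"] + (stretch - 1) * 1.0
    bonds <- data.frame(i = 1:(nat - 1), j = 2:nat)
    species_record(molecule_id = id,
                   parent_elements = c("C", "C", "C", "O"),
                   parent_geometry = parent, reduced_geometry = reduced,
                   bonds = bonds,
                   frequencies = list(parent = freqs, reduced = freqs),
                   s_squared = s_squared, multiplicity = mult,
                   bulk_electrostatic = bulk,
                   expected_outcome = expected)
  }
  recs <- list(
    mk("bond_offender", stretch = 1.5, expected = "bond_change"),
    mk("spin_offender", s_squared = 0.90, expected = "spin_contamination"),
    mk("freq_offender", freqs = c(-25, 250, 800),
       expected = "imaginary_frequency"),
    mk("electro_offender", bulk = -5.0, expected = "electrostatic_range")
  )
  clean <- lapply(seq_len(n_clean), function(i)
    mk(sprintf("clean%02d", i),
       stretch = 1 + stats::runif(1, 0, 0.1),
       s_squared = 0.75 * (1 + stats::runif(1, 0, 0.05)),
       bulk = stats::runif(1, -3.5, -0.3)))
  recs <- c(recs, clean)
  recs[sample(length(recs))]
}
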