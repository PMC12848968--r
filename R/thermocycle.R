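#' Physical constants for redox thermochemistry
#'
#' Returns the constants used throughout the reduction-potential
#' arithmetic: Faraday's constant and the absolute potential of the
#' standard hydrogen electrode (SHE) under the Fermi-Dirac electron
#' convention. Values are overridable only through the arguments of this
#' constructor; nothing else in the package mutates them.
#'
#' @param faraday Faraday's constant in C mol^-1.
#' @param e_ref_she Absolute electrode potential of the SHE in volts
#'   (negative by convention: the energy of an electron at the SHE level
#'   relative to vacuum).
#' @param g_electron Gibbs free energy of the gas-phase electron in
#'   J mol^-1 under the electron convention (Fermi-Dirac statistics).
#' @return A list of class `"redox_constants"`.
#' @examples
#' k <- redox_constants()
#' k$faraday
#' @export
redox_constants <- function(faraday = 96485.3383,
                            e_ref_she = -4.48,
                            g_electron = -3632) {
  stopifnot(is.finite(faraday), faraday > 0,
            is.finite(e_ref_she), is.finite(g_electron))
  structure(list(faraday = faraday, e_ref_she = e_ref_she,
                 g_electron = g_electron),
            class = "redox_constants")
}

#' Thermodynamic-cycle components of a one-electron reduction
#'
#' Bundles the four free-energy terms of the reduction thermodynamic
#' cycle for A + e- -> A-: gas-phase Gibbs free energies of the parent
#' and reduced species and their solvation free energies, plus the
#' gas-phase electron free energy. All energies are in J mol^-1.
#'
#' @param g_gas_parent,g_gas_reduced Gas-phase Gibbs free energies.
#' @param dg_solv_parent,dg_solv_reduced Solvation free energies.
#' @param g_electron Gas-phase electron free energy (electron
#'   convention); defaults to -3632 J mol^-1.
#' @return A list of class `"thermo_components"`.
#' @export
thermo_components <- function(g_gas_parent, g_gas_reduced,
                              dg_solv_parent, dg_solv_reduced,
                              g_electron = -3632) {
  vals <- c(g_gas_parent, g_gas_reduced, dg_solv_parent,
            dg_solv_reduced, g_electron)
  if (!all(is.finite(vals)))
    stop("all thermodynamic components must be finite")
  structure(list(g_gas_parent = g_gas_parent,
                 g_gas_reduced = g_gas_reduced,
                 dg_solv_parent = dg_solv_parent,
                 dg_solv_reduced = dg_solv_reduced,
                 g_electron = g_electron),
            class = "thermo_components")
}

#' Gibbs free energy of reduction from cycle components
#'
#' Assembles the solution-phase reduction free energy
#' \deqn{\Delta G_{red}(solv) = [G_{gas}(A^-) + \Delta G_{solv}(A^-)]
#'   - [G_{gas}(A) + \Delta G_{solv}(A)] - G(e^-)}
#' The electron is a reactant, so its free energy is subtracted: with
#' all molecular terms zero and the default electron convention value,
#' the result is +3632 J mol^-1.
#'
#' @param components A [thermo_components()] object.
#' @return Reduction free energy in J mol^-1.
#' @export
delta_g_reduction <- function(components) {
  stopifnot(inherits(components, "thermo_components"))
  with(components,
       (g_gas_reduced + dg_solv_reduced) -
         (g_gas_parent + dg_solv_parent) - g_electron)
}

#' Reduction potential from the reduction free energy
#'
#' Applies \deqn{E_{red} = -\Delta G_{red}/F - E_{REF}} where `F` is
#' Faraday's constant and `E_REF` the absolute potential of the
#' reference electrode (for the SHE, -4.48 V under Fermi-Dirac
#' statistics, so a zero reduction free energy maps to +4.48 V vs SHE).
#'
#' @param dg_red Reduction free energy in J mol^-1.
#' @param ref A [reference_electrode()] or the name of a registered
#'   electrode (default `"SHE"`).
#' @param constants A [redox_constants()] object.
#' @return Reduction potential in volts versus `ref`.
#' @examples
#' reduction_potential(0)                   # 4.48
#' reduction_potential(-96485.3383)         # 5.48
#' @export
reduction_potential <- function(dg_red, ref = "SHE",
                                constants = redox_constants()) {
  if (!all(is.finite(dg_red))) stop("dg_red must be finite")
  if (is.character(ref)) ref <- get_reference_electrode(ref, constants)
  stopifnot(inherits(ref, "reference_electrode"))
  -dg_red / constants$faraday - ref$e_ref
}

#' Adiabatic electron affinity from gas-phase free energies
#'
#' EA = G_gas(parent) - G_gas(reduced), converted from J mol^-1 to eV
#' per particle; positive when the reduced species is lower in free
#' energy.
#'
#' @param g_gas_parent,g_gas_reduced Gas-phase Gibbs free energies in
#'   J mol^-1.
#' @param constants A [redox_constants()] object (supplies Faraday's
#'   constant, numerically equal to the J mol^-1 content of 1 eV per
#'   particle).
#' @return Electron affinity in eV.
#' @export
electron_affinity <- function(g_gas_parent, g_gas_reduced,
                              constants = redox_constants()) {
  jmol_to_ev(g_gas_parent - g_gas_reduced, constants)
}

#' Convert molar energies to eV per particle and back
#'
#' One eV per particle corresponds to F J mol^-1 (F = N_A e).
#'
#' @param x Energy values.
#' @param constants A [redox_constants()] object.
#' @return Converted values.
#' @export
jmol_to_ev <- function(x, constants = redox_constants()) {
  x / constants$faraday
}

#' @rdname jmol_to_ev
#' @export
ev_to_jmol <- function(x, constants = redox_constants()) {
  x * constants$faraday
}

#' Reduction potentials from a component table
#'
#' Reads a CSV of thermodynamic-cycle components with columns
#' `species_id`, `role` (`parent`/`reduced`), `g_gas`, `dg_solv` and
#' optionally `solvent`, pairs parent and reduced rows per
#' (species, solvent), and returns the assembled reduction free energy
#' and potential per pair.
#'
#' @param path CSV file path.
#' @param ref Reference electrode name or object.
#' @param constants A [redox_constants()] object.
#' @return A data.frame with columns `species_id`, `solvent`,
#'   `dg_red_jmol`, `e_red_volts`.
#' @export
potentials_from_components <- function(path, ref = "SHE",
                                       constants = redox_constants()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "role", "g_gas", "dg_solv")
  if (!all(need %in% names(tab)))
    stop("component table must have columns: ",
         paste(need, collapse = ", "))
  if (is.null(tab$solvent)) tab$solvent <- ""
  key <- interaction(tab$species_id, tab$solvent, drop = TRUE)
  out <- lapply(split(tab, key), function(grp) {
    p <- grp[grp$role == "parent", , drop = FALSE]
    r <- grp[grp$role == "reduced", , drop = FALSE]
    if (nrow(p) != 1L || nrow(r) != 1L)
      stop("species ", grp$species_id[1], "/", grp$solvent[1],
           ": need exactly one parent and one reduced row")
    comp <- thermo_components(p$g_gas, r$g_gas, p$dg_solv, r$dg_solv,
                              g_electron = constants$g_electron)
    dg <- delta_g_reduction(comp)
    data.frame(species_id = grp$species_id[1], solvent = grp$solvent[1],
               dg_red_jmol = dg,
               e_red_volts = reduction_potential(dg, ref, constants),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
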