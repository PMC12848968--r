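#' Solvent descriptor specification
#'
#' The only solvent representation the predictor sees: the static
#' dielectric constant (25 C) and the refractive index. These two
#' scalars are what allow the solvent-conditioned model to generalize
#' to solvents absent from training.
#'
#' @param name Solvent name.
#' @param epsilon Static dielectric constant (> 1).
#' @param refractive_index Refractive index (>= 1).
#' @return A list of class `"solvent_spec"`.
#' @export
solvent_spec <- function(name, epsilon, refractive_index) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(epsilon), epsilon > 1,
            is.finite(refractive_index), refractive_index >= 1)
  structure(list(name = name, epsilon = epsilon,
                 refractive_index = refractive_index),
            class = "solvent_spec")
}

# Literature 25 C values; user-overridable through solvent_registry().
.default_solvents <- function() {
  list(
    acetonitrile      = solvent_spec("acetonitrile", 35.9, 1.344),
    water             = solvent_spec("water", 78.4, 1.333),
    tetrahydrofuran   = solvent_spec("tetrahydrofuran", 7.43, 1.407),
    dimethylsulfoxide = solvent_spec("dimethylsulfoxide", 46.8, 1.479),
    dimethylformamide = solvent_spec("dimethylformamide", 36.7, 1.430)
  )
}

.solvent_aliases <- c(
  acn = "acetonitrile", mecn = "acetonitrile",
  acetonitrile = "acetonitrile",
  h2o = "water", water = "water",
  thf = "tetrahydrofuran", tetrahydrofuran = "tetrahydrofuran",
  dmso = "dimethylsulfoxide", dimethylsulfoxide = "dimethylsulfoxide",
  "dimethyl sulfoxide" = "dimethylsulfoxide",
  dmf = "dimethylformamide", dimethylformamide = "dimethylformamide"
)

#' Solvent registry
#'
#' The default registry covers the five training solvents
#' (acetonitrile, water, tetrahydrofuran, DMSO, DMF) with standard 25 C
#' literature dielectric constants and refractive indices. Extra
#' solvents can be appended without touching the defaults, and default
#' values can be overridden per solvent.
#'
#' @param extra Optional named list of [solvent_spec()] objects to add
#'   or override.
#' @return Named list of `solvent_spec` objects.
#' @export
solvent_registry <- function(extra = NULL) {
  reg <- .default_solvents()
  if (!is.null(extra)) {
    stopifnot(is.list(extra))
    for (s in extra) {
      stopifnot(inherits(s, "solvent_spec"))
      reg[[tolower(s$name)]] <- s
    }
  }
  reg
}

#' Look up a solvent by name or abbreviation
#'
#' Case-insensitive; common abbreviations (ACN, H2O, THF, DMSO, DMF)
#' are accepted.
#'
#' @param name Solvent name or abbreviation.
#' @param registry A registry from [solvent_registry()].
#' @return A [solvent_spec()] object.
#' @export
get_solvent <- function(name, registry = solvent_registry()) {
  if (inherits(name, "solvent_spec")) return(name)
  key <- tolower(trimws(name))
  if (!is.na(.solvent_aliases[key])) key <- .solvent_aliases[[key]]
  if (!key %in% names(registry))
    stop("unknown solvent '", name, "'; registered solvents: ",
         paste(names(registry), collapse = ", "))
  registry[[key]]
}

# Reference scaling constants for the descriptor transform, frozen from
# the default five-solvent registry so that a new solvent is expressed
# on the same scale as the training solvents.
.descriptor_scale <- list(eps_min = 7.43, eps_max = 78.4,
                          n_min = 1.333, n_max = 1.479)

#' Model-input descriptor vector for a solvent
#'
#' Deterministic transform of (epsilon, n) into the two-component
#' vector fed to the solvent head of the network. Two transforms are
#' available: `"minmax"` (default) rescales raw epsilon and n over
#' fixed reference bounds frozen from the default registry;
#' `"onsager"` uses the reaction-field forms (eps-1)/(eps+2) and
#' (n^2-1)/(n^2+2). Both are strictly increasing in each argument and
#' vanish at the vacuum point (epsilon = 1, n = 1).
#'
#' @param solvent A [solvent_spec()] object (or name).
#' @param transform `"minmax"` or `"onsager"`.
#' @return Numeric length-2 vector.
#' @export
descriptor_vector <- function(solvent, transform = c("minmax", "onsager")) {
  transform <- match.arg(transform)
  s <- get_solvent(solvent)
  if (transform == "minmax") {
    sc <- .descriptor_scale
    c((s$epsilon - 1) / (sc$eps_max - 1),
      (s$refractive_index - 1) / (sc$n_max - 1))
  } else {
    c((s$epsilon - 1) / (s$epsilon + 2),
      (s$refractive_index^2 - 1) / (s$refractive_index^2 + 2))
  }
}

#' Reference electrodes and potential-scale conversion
#'
#' A reference electrode is characterised by its absolute potential
#' `e_ref` in volts (the SHE value, -4.48 V, comes from the Fermi-Dirac
#' electron convention). Conversions between a relative scale and the
#' absolute scale are affine:
#' `absolute = relative + offset`, with `offset = -e_ref`.
#' Ferrocene and lithium couples have no universally agreed absolute
#' value; their offsets are explicit configuration with documented
#' literature defaults (Fc0/Fc+ approx +0.40 V vs SHE in acetonitrile;
#' Li/Li+ approx -3.04 V vs SHE).
#'
#' @param name Electrode name.
#' @param e_ref Absolute electrode potential in volts (negative).
#' @param solvent_scope Optional solvent the value is quoted in.
#' @return A list of class `"reference_electrode"`.
#' @export
reference_electrode <- function(name, e_ref, solvent_scope = NA_character_) {
  stopifnot(is.finite(e_ref))
  structure(list(name = name, e_ref = e_ref,
                 offset_volts = -e_ref, solvent_scope = solvent_scope),
            class = "reference_electrode")
}

#' @rdname reference_electrode
#' @param constants A [redox_constants()] object (supplies the SHE
#'   absolute potential).
#' @export
electrode_registry <- function(constants = redox_constants()) {
  she <- constants$e_ref_she
  list(
    she = reference_electrode("SHE", she, "acetonitrile"),
    fc  = reference_electrode("Fc", she - 0.40, "acetonitrile"),
    li  = reference_electrode("Li", she + 3.04)
  )
}

#' @rdname reference_electrode
#' @export
get_reference_electrode <- function(name, constants = redox_constants()) {
  if (inherits(name, "reference_electrode")) return(name)
  reg <- electrode_registry(constants)
  key <- tolower(trimws(sub("0?/.*$", "", name)))
  key <- c(she = "she", fc = "fc", ferrocene = "fc",
           li = "li", lithium = "li")[key]
  if (is.na(key) || !key %in% names(reg))
    stop("unknown reference electrode '", name,
         "'; registered: SHE, Fc, Li")
  reg[[key]]
}

#' Convert potentials between a reference-electrode scale and the
#' absolute scale
#'
#' `to_absolute(x, ref)` returns `x + offset_volts`;
#' `to_relative(x, ref)` is its exact inverse.
#'
#' @param potential Potential(s) in volts.
#' @param ref A [reference_electrode()] or registered name.
#' @return Converted potential(s) in volts.
#' @examples
#' to_absolute(0, "SHE")   # 4.48
#' @export
to_absolute <- function(potential, ref) {
  ref <- get_reference_electrode(ref)
  potential + ref$offset_volts
}

#' @rdname to_absolute
#' @export
to_relative <- function(potential, ref) {
  ref <- get_reference_electrode(ref)
  potential - ref$offset_volts
}
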