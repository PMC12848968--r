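#' Species record for data-set curation
#'
#' One candidate molecule's parent/reduced geometries and the
#' quantities the stability filters inspect.
#'
#' @param molecule_id Identifier.
#' @param parent_elements Element symbols (same atom order in both
#'   geometries).
#' @param parent_geometry,reduced_geometry Numeric matrices (atoms x 3,
#'   Angstrom).
#' @param bonds Data frame with columns `i`, `j`: the parent
#'   connectivity (bonds broken upon reduction then register as large
#'   length changes, which is intended).
#' @param frequencies List with numeric vectors `parent` and `reduced`
#'   (cm^-1); negative values denote imaginary modes.
#' @param s_squared Spin-squared expectation value of the (open-shell)
#'   reduced species.
#' @param multiplicity Spin multiplicity of the reduced species.
#' @param bulk_electrostatic Bulk electrostatic contribution of the
#'   reaction-field treatment (eV).
#' @param expected_outcome Optional label used by fixture generators.
#' @return A list of class `"species_record"`.
#' @export
species_record <- function(molecule_id, parent_elements,
                           parent_geometry, reduced_geometry, bonds,
                           frequencies = list(parent = numeric(),
                                              reduced = numeric()),
                           s_squared = NA_real_, multiplicity = 2L,
                           bulk_electrostatic = NA_real_,
                           expected_outcome = NA_character_) {
  parent_geometry <- as.matrix(parent_geometry)
  reduced_geometry <- as.matrix(reduced_geometry)
  if (nrow(parent_geometry) != nrow(reduced_geometry))
    stop("parent and reduced geometries must have the same atom count")
  if (nrow(parent_geometry) != length(parent_elements))
    stop("element list and geometry are inconsistent")
  stopifnot(multiplicity >= 1)
  structure(list(molecule_id = molecule_id,
                 parent_elements = parent_elements,
                 parent_geometry = parent_geometry,
                 reduced_geometry = reduced_geometry,
                 bonds = bonds, frequencies = frequencies,
                 s_squared = s_squared,
                 multiplicity = as.integer(multiplicity),
                 bulk_electrostatic = bulk_electrostatic,
                 expected_outcome = expected_outcome),
            class = "species_record")
}

#' Maximum relative bond-length change upon reduction
#'
#' For each bond of the parent connectivity, the relative length change
#' |r_reduced - r_parent| / r_parent is computed; the maximum over
#' bonds is returned. Species exceeding 40% are curated out as
#' unstable (intramolecular rearrangement or decomposition upon
#' reduction).
#'
#' @param parent_geometry,reduced_geometry Atom x 3 coordinate
#'   matrices with identical atom ordering.
#' @param bonds Data frame with columns `i`, `j`.
#' @return Maximum relative bond-length change (fraction).
#' @export
max_bond_change <- function(parent_geometry, reduced_geometry, bonds) {
  parent_geometry <- as.matrix(parent_geometry)
  reduced_geometry <- as.matrix(reduced_geometry)
  if (nrow(parent_geometry) != nrow(reduced_geometry))
    stop("mismatched atom counts between parent and reduced geometries")
  if (nrow(bonds) == 0L) return(0)
  blen <- function(geom, k)
    sqrt(sum((geom[bonds$i[k], ] - geom[bonds$j[k], ])^2))
  changes <- vapply(seq_len(nrow(bonds)), function(k) {
    rp <- blen(parent_geometry, k)
    rr <- blen(reduced_geometry, k)
    abs(rr - rp) / rp
  }, numeric(1))
  max(changes)
}

#' Relative spin-contamination of an open-shell species
#'
#' The single-reference expectation is S(S+1) with
#' S = (multiplicity - 1)/2; the deviation is
#' s_squared / S(S+1) - 1. Species above 10% deviation are curated
#' out as spin-contaminated.
#'
#' @param s_squared Spin-squared expectation value.
#' @param multiplicity Spin multiplicity (>= 2 for open shell).
#' @return Fractional deviation (0 for an ideal species).
#' @export
s_squared_deviation <- function(s_squared, multiplicity) {
  stopifnot(multiplicity >= 1)
  if (multiplicity == 1L) {
    if (!is.na(s_squared) && s_squared != 0)
      stop("closed-shell species (multiplicity 1) with nonzero <S^2>: inconsistent record")
    return(0)
  }
  S <- (multiplicity - 1) / 2
  ideal <- S * (S + 1)
  s_squared / ideal - 1
}

#' Default curation thresholds
#'
#' 40% maximum bond-length change, 10% spin-contamination deviation,
#' no imaginary frequencies (tolerance 0 cm^-1), and a bulk
#' electrostatics keep-range of [-4.0, -0.1] eV (boundary values are
#' kept; values outside are removed).
#'
#' @return Named list of thresholds.
#' @export
curation_thresholds <- function() {
  list(bond_change = 0.40, spin = 0.10, freq_tol = 0,
       electrostatic = c(-4.0, -0.1))
}

.check_record <- function(rec, th) {
  # first failing rule wins; rule order: bond change, spin
  # contamination, imaginary frequency, electrostatic range
  res <- tryCatch({
    bc <- max_bond_change(rec$parent_geometry, rec$reduced_geometry,
                          rec$bonds)
    if (bc > th$bond_change) return("bond_change")
    if (rec$multiplicity > 1L || !is.na(rec$s_squared)) {
      if (is.na(rec$s_squared)) return("error:missing_s_squared")
      dev <- s_squared_deviation(rec$s_squared, rec$multiplicity)
      if (dev > th$spin) return("spin_contamination")
    }
    freqs <- unlist(rec$frequencies)
    if (length(freqs) == 0L) return("error:missing_frequencies")
    if (any(freqs < -th$freq_tol)) return("imaginary_frequency")
    if (is.na(rec$bulk_electrostatic))
      return("error:missing_bulk_electrostatic")
    be <- rec$bulk_electrostatic
    if (be < th$electrostatic[1] || be > th$electrostatic[2])
      return("electrostatic_range")
    "kept"
  }, error = function(e) paste0("error:", conditionMessage(e)))
  res
}

#' Apply the data-set curation filters
#'
#' Each record is checked, in order, against the bond-length-change,
#' spin-contamination, imaginary-frequency and bulk-electrostatics
#' filters; removed records carry the first failing rule's tag. A
#' record missing a field needed by a requested filter gets an error
#' tag rather than a silent pass. Input order is preserved and
#' kept + removed partitions the input.
#'
#' @param records List of [species_record()]s.
#' @param thresholds See [curation_thresholds()].
#' @return List with `kept` (list of records), `removed` (data.frame
#'   `molecule_id`, `reason`), and `report` (data.frame over all
#'   records in input order).
#' @export
apply_filters <- function(records, thresholds = curation_thresholds()) {
  stopifnot(is.list(records))
  tags <- vapply(records, .check_record, character(1), th = thresholds)
  ids <- vapply(records, function(r) r$molecule_id, character(1))
  report <- data.frame(molecule_id = ids, outcome = tags,
                       stringsAsFactors = FALSE)
  keep <- tags == "kept"
  list(kept = records[keep],
       removed = data.frame(molecule_id = ids[!keep],
                            reason = tags[!keep],
                            stringsAsFactors = FALSE),
       report = report)
}

#' Read and write XYZ geometry files
#'
#' Minimal XYZ support for curation inputs: atom count line, comment
#' line, then `element x y z` rows.
#'
#' @param path File path.
#' @return `read_xyz()`: list with `elements` and `coords`;
#'   `write_xyz()`: `path`, invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2L)
    stop("malformed XYZ file: ", path)
  rows <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  elements <- vapply(rows, `[[`, character(1), 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  colnames(coords) <- c("x", "y", "z")
  list(elements = elements, coords = coords)
}

#' @rdname read_xyz
#' @param elements Element symbols.
#' @param coords Atoms x 3 coordinate matrix.
#' @param comment Comment line.
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  coords <- as.matrix(coords)
  stopifnot(length(elements) == nrow(coords))
  lines <- c(length(elements), comment,
             sprintf("%-3s %14.8f %14.8f %14.8f", elements,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}
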