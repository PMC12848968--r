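# Editable kekulized molecule representation used by the evolutionary
# search and the synthetic molecule generator: element symbols plus an
# integer-order bond table. Hydrogens are implicit and follow from the
# typical-valence model below, which is also what gates mutation
# validity.

.typical_valence <- c(C = 4, N = 3, O = 2, F = 1, S = 2, Cl = 1, Br = 1)

#' Editable molecule
#'
#' A minimal kekulized molecule: element symbols and integer bond
#' orders. Used as the substrate of graph mutations; convert to/from
#' SMILES with [smiles_to_edit_mol()] and [edit_mol_to_smiles()].
#'
#' @param elements Character vector of element symbols.
#' @param bonds Data frame with integer columns `i`, `j`, `order`
#'   (1, 2 or 3).
#' @return An object of class `"edit_mol"`.
#' @export
edit_mol <- function(elements,
                     bonds = data.frame(i = integer(), j = integer(),
                                        order = integer())) {
  stopifnot(length(elements) >= 1L,
            all(c("i", "j", "order") %in% names(bonds)))
  structure(list(elements = elements,
                 bonds = bonds[, c("i", "j", "order"), drop = FALSE]),
            class = "edit_mol")
}

.used_valence <- function(mol) {
  v <- numeric(length(mol$elements))
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      v[b$i[k]] <- v[b$i[k]] + b$order[k]
      v[b$j[k]] <- v[b$j[k]] + b$order[k]
    }
  }
  v
}

.free_valence <- function(mol, valences = .typical_valence) {
  cap <- valences[mol$elements]
  if (anyNA(cap))
    stop("no valence rule for element(s): ",
         paste(unique(mol$elements[is.na(cap)]), collapse = ", "))
  unname(cap) - .used_valence(mol)
}

.mol_connected <- function(mol) {
  n <- length(mol$elements)
  if (n == 1L) return(TRUE)
  if (nrow(mol$bonds) == 0L) return(FALSE)
  gr <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                    directed = FALSE)
  if (igraph::vcount(gr) < n)
    gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  igraph::components(gr)$no == 1L
}

#' Serialize an editable molecule as a V2000 molblock
#'
#' Coordinates are zero; connectivity and bond orders carry the full
#' structure.
#'
#' @param mol An [edit_mol()].
#' @return A single molblock string.
#' @export
mol_to_molblock <- function(mol) {
  n <- length(mol$elements); m <- nrow(mol$bonds)
  lines <- c("", " redoxgnn", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     0, 0, 0, mol$elements),
             if (m) sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                            mol$bonds$order),
             "M  END", "$$$$")
  paste(lines, collapse = "\n")
}

#' Convert an editable molecule to canonical SMILES
#'
#' @param mol An [edit_mol()].
#' @return Canonical SMILES string.
#' @export
edit_mol_to_smiles <- function(mol) {
  out <- trimws(.ob_convert("MOL", "CAN", mol_to_molblock(mol)))
  if (!nzchar(out)) stop("molblock conversion failed")
  out
}

#' Parse a SMILES string into an editable molecule
#'
#' The molecule is kekulized (integer bond orders); hydrogens are
#' implicit.
#'
#' @param smiles SMILES string.
#' @return An [edit_mol()].
#' @export
smiles_to_edit_mol <- function(smiles) {
  sdf <- .ob_convert("SMI", "SDF", canonical_smiles(smiles))
  if (!nzchar(trimws(sdf))) stop("cannot parse SMILES: '", smiles, "'")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  nat <- as.integer(substr(lines[4], 1, 3))
  nbo <- as.integer(substr(lines[4], 4, 6))
  if (is.na(nbo) || nbo == 0L) {
    # bondless molecule: single heavy atom (degenerate molblock that
    # SDF container parsers reject)
    el <- trimws(substr(lines[5:(4 + nat)], 32, 34))
    return(edit_mol(el[el != "H"]))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf, tf)
  set <- ChemmineR::read.SDFset(tf)
  ab <- ChemmineR::atomblock(set[[1]])
  bb <- ChemmineR::bondblock(set[[1]])
  el <- sub("_.*$", "", rownames(ab))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  keep <- el != "H"
  if (!all(keep)) {
    remap <- cumsum(keep)
    hb <- keep[bonds$i] & keep[bonds$j]
    bonds <- data.frame(i = remap[bonds$i[hb]], j = remap[bonds$j[hb]],
                        order = bonds$order[hb])
    el <- el[keep]
  }
  edit_mol(el, bonds)
}

# Validity under the evolution constraints: known valences respected,
# connected, allowed elements, size cap.
.mol_valid <- function(mol, allowed_elements, max_heavy) {
  if (length(mol$elements) < 1L) return("empty graph")
  if (length(mol$elements) > max_heavy) return("size")
  if (!all(mol$elements %in% allowed_elements)) return("element")
  fv <- tryCatch(.free_valence(mol), error = function(e) NULL)
  if (is.null(fv) || any(fv < 0)) return("valence")
  if (!.mol_connected(mol)) return("disconnected")
  TRUE
}
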