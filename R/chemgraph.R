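# Element property tables: atomic mass (u), Bondi van der Waals radius
# (A), Cordero covalent radius (A). Scaled features are min-max over the
# active vocabulary, so the constants below are the only frozen source.
.element_props <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  mass    = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
              28.085, 30.974, 32.06, 35.45, 79.904, 126.904),
  vdw     = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47,
              2.10, 1.80, 1.80, 1.75, 1.85, 1.98),
  covalent = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57,
               1.11, 1.07, 1.05, 1.02, 1.20, 1.39),
  stringsAsFactors = FALSE
)

#' Default element vocabulary
#'
#' The floor is the element set used by the inverse-design constraints
#' (C, N, O, F, S, Cl, Br) plus hydrogen; pass `extra` to extend it.
#' Unknown elements in a molecule are an error, never an "other"
#' bucket.
#'
#' @param extra Character vector of additional element symbols.
#' @return Character vector of element symbols.
#' @export
element_vocabulary <- function(extra = character()) {
  vocab <- unique(c("H", "C", "N", "O", "F", "S", "Cl", "Br", extra))
  unknown <- setdiff(vocab, .element_props$element)
  if (length(unknown))
    stop("no property data for element(s): ",
         paste(unknown, collapse = ", "))
  vocab
}

.ob_convert <- function(from, to, source, add_h = FALSE) {
  tryCatch({
    if (add_h)
      suppressWarnings(ChemmineOB::convertFormat(
        from, to, source = source,
        options = data.frame(names = "h", args = "")))
    else
      suppressWarnings(ChemmineOB::convertFormat(from, to, source = source))
  }, error = function(e) "")
}

#' Canonicalize a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- .ob_convert("SMI", "CAN", smiles)
  out <- trimws(out)
  if (!nzchar(out))
    stop("cannot parse SMILES: '", smiles, "'")
  out
}

.parse_mol2 <- function(txt) {
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  bio3d::read.mol2(tf)
}

#' Featurize a SMILES string into a molecular graph
#'
#' Converts a SMILES string into a heavy-atom molecular graph carrying
#' the atom features (element index, heavy-neighbor count, ring
#' membership, aromaticity, scaled atomic mass, scaled van der Waals
#' radius, scaled covalent radius, valence) and bond features (bond
#' type, conjugation, ring membership) consumed by the predictor.
#' Hydrogens are implicit: they contribute to the valence feature but
#' are not graph nodes. Multi-fragment SMILES (salts) are rejected.
#'
#' @param smiles A single SMILES string.
#' @param vocabulary Element vocabulary from [element_vocabulary()].
#' @return An object of class `"mol_graph"`: a list with `smiles`
#'   (canonical), `nodes` and `edges` data frames, and `n_heavy`.
#' @examples
#' \donttest{
#' g <- featurize("c1ccccc1")
#' g$n_heavy            # 6
#' nrow(g$edges)        # 6
#' }
#' @export
featurize <- function(smiles, vocabulary = element_vocabulary()) {
  can <- canonical_smiles(smiles)
  if (grepl(".", can, fixed = TRUE))
    stop("multi-fragment SMILES rejected: '", smiles, "'")
  m <- .parse_mol2(.ob_convert("SMI", "MOL2", can, add_h = TRUE))
  if (is.null(m$atom) || nrow(m$atom) == 0L)
    stop("cannot parse SMILES: '", smiles, "'")

  elety <- m$atom$elety
  element <- sub("\\..*$", "", elety)
  aromatic_atom <- grepl("\\.ar$", elety)
  is_h <- element == "H"

  unknown <- setdiff(unique(element), vocabulary)
  if (length(unknown))
    stop("element(s) outside vocabulary: ",
         paste(unknown, collapse = ", "))

  bonds <- m$bond
  border <- tolower(bonds$type)
  order_num <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5,
                 "am" = 1, "du" = 1, "un" = 1)[border]
  if (anyNA(order_num))
    stop("unsupported bond type in '", smiles, "'")

  heavy_idx <- which(!is_h)
  n <- length(heavy_idx)
  if (n == 0L) stop("no heavy atoms in '", smiles, "'")
  remap <- integer(nrow(m$atom))
  remap[heavy_idx] <- seq_len(n)

  # hydrogen counts and total valence per heavy atom
  n_h <- numeric(n)
  valence <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$origin[k]; b <- bonds$target[k]; o <- order_num[k]
    for (end in c(a, b)) {
      other <- if (end == a) b else a
      if (!is_h[end]) {
        valence[remap[end]] <- valence[remap[end]] + o
        if (is_h[other]) n_h[remap[end]] <- n_h[remap[end]] + 1
      }
    }
  }

  hb <- !is_h[bonds$origin] & !is_h[bonds$target]
  ei <- remap[bonds$origin[hb]]
  ej <- remap[bonds$target[hb]]
  eo <- order_num[hb]
  etype_chr <- border[hb]
  me <- length(ei)
  if (any(ei == ej)) stop("self-loop bond in '", smiles, "'")

  # ring membership: an edge is in a ring iff it is not a bridge
  in_ring_edge <- rep(FALSE, me)
  if (me > 0L) {
    gr <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
    if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
    if (igraph::components(gr)$no > 1L)
      stop("disconnected heavy-atom graph in '", smiles, "'")
    br <- igraph::bridges(gr)
    bridge_ids <- as.integer(br)
    in_ring_edge <- !(seq_len(me) %in% bridge_ids)
  }
  in_ring_atom <- rep(FALSE, n)
  if (me > 0L) {
    ring_atoms <- unique(c(ei[in_ring_edge], ej[in_ring_edge]))
    in_ring_atom[ring_atoms] <- TRUE
  }

  # heavy-neighbor count
  n_heavy_neighbors <- tabulate(c(ei, ej), nbins = n)

  # conjugation: aromatic bonds are conjugated; otherwise a bond is
  # conjugated when each endpoint carries a multiple bond other than
  # the bond itself (the sp2/sp adjacency rule)
  multi <- eo > 1
  conj <- rep(FALSE, me)
  if (me > 0L) {
    for (k in seq_len(me)) {
      if (etype_chr[k] == "ar") { conj[k] <- TRUE; next }
      ends_ok <- vapply(c(ei[k], ej[k]), function(v) {
        inc <- which((ei == v | ej == v) & seq_len(me) != k)
        any(multi[inc]) || any(in_ring_edge[inc] & etype_chr[inc] == "ar")
      }, logical(1))
      conj[k] <- all(ends_ok)
    }
  }

  hel <- element[heavy_idx]
  props <- .element_props[match(vocabulary, .element_props$element), ]
  sc <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  mass_s <- sc(props$mass); vdw_s <- sc(props$vdw); cov_s <- sc(props$covalent)
  pe <- match(hel, vocabulary)

  bond_type <- ifelse(etype_chr == "ar", 4L,
                      ifelse(etype_chr == "3", 3L,
                             ifelse(etype_chr == "2", 2L, 1L)))

  nodes <- data.frame(
    element = hel,
    element_index = pe,
    n_heavy_neighbors = as.integer(n_heavy_neighbors),
    in_ring = in_ring_atom,
    aromatic = aromatic_atom[heavy_idx],
    mass_scaled = mass_s[pe],
    vdw_radius_scaled = vdw_s[pe],
    covalent_radius_scaled = cov_s[pe],
    valence = valence,
    n_h = as.integer(n_h),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    i = as.integer(ei), j = as.integer(ej),
    bond_type = bond_type, conjugated = conj, in_ring = in_ring_edge
  )
  structure(list(smiles = can, nodes = nodes, edges = edges,
                 n_heavy = n, vocabulary = vocabulary),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", x$smiles, "\n")
  cat("  ", x$n_heavy, "heavy atoms,", nrow(x$edges), "bonds\n")
  invisible(x)
}

#' Atom and bond feature matrices of a molecular graph
#'
#' `atom_features()` returns one row per heavy atom: one-hot element
#' over the vocabulary followed by heavy-neighbor count, ring flag,
#' aromatic flag, scaled mass, scaled van der Waals radius, scaled
#' covalent radius, and valence. `bond_features()` returns one row per
#' (undirected) bond: one-hot bond type over
#' \{single, double, triple, aromatic\} followed by conjugation and
#' ring flags.
#'
#' @param g A [featurize()]d `mol_graph`.
#' @return Numeric matrix.
#' @export
atom_features <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  V <- length(g$vocabulary)
  n <- g$n_heavy
  onehot <- matrix(0, n, V)
  onehot[cbind(seq_len(n), g$nodes$element_index)] <- 1
  cbind(onehot,
        g$nodes$n_heavy_neighbors,
        as.numeric(g$nodes$in_ring),
        as.numeric(g$nodes$aromatic),
        g$nodes$mass_scaled,
        g$nodes$vdw_radius_scaled,
        g$nodes$covalent_radius_scaled,
        g$nodes$valence)
}

#' @rdname atom_features
#' @export
bond_features <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  m <- nrow(g$edges)
  onehot <- matrix(0, m, 4)
  if (m > 0) onehot[cbind(seq_len(m), g$edges$bond_type)] <- 1
  cbind(onehot,
        as.numeric(g$edges$conjugated),
        as.numeric(g$edges$in_ring))
}

#' Directed edge expansion of a molecular graph
#'
#' Each undirected bond yields two directed entries sharing one feature
#' record, the form consumed by message passing.
#'
#' @param g A `mol_graph`.
#' @return List with integer vectors `src`, `dst`, `eidx` (index into
#'   the undirected edge list), each of length twice the bond count.
#' @export
to_directed <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  m <- nrow(g$edges)
  if (m == 0L) return(list(src = integer(), dst = integer(),
                           eidx = integer()))
  list(src = c(g$edges$i, g$edges$j),
       dst = c(g$edges$j, g$edges$i),
       eidx = c(seq_len(m), seq_len(m)))
}

#' Read a molecule table
#'
#' Reads a CSV with columns `id`, `smiles` and zero or more target
#' columns. Rows whose SMILES cannot be parsed are skipped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @return A data.frame of the valid rows, with attribute `n_skipped`.
#' @export
read_molecule_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || !all(c("id", "smiles") %in% names(tab)))
    stop("molecule table must be a non-empty CSV with columns 'id' and 'smiles'")
  ok <- vapply(tab$smiles, function(s)
    !inherits(tryCatch(canonical_smiles(s), error = identity), "error"),
    logical(1))
  if (any(!ok))
    message(sum(!ok), " row(s) with unparsable SMILES skipped")
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Serialize molecular graphs to and from JSON
#'
#' @param g A `mol_graph`.
#' @param path Output/input file path.
#' @return `write_mol_graph()` returns `path` invisibly;
#'   `read_mol_graph()` returns a `mol_graph`.
#' @export
write_mol_graph <- function(g, path) {
  stopifnot(inherits(g, "mol_graph"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mol_graph
#' @export
read_mol_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nodes <- as.data.frame(x$nodes)
  x$edges <- as.data.frame(x$edges)
  if (nrow(x$edges) == 0L)
    x$edges <- data.frame(i = integer(), j = integer(),
                          bond_type = integer(), conjugated = logical(),
                          in_ring = logical())
  structure(x, class = "mol_graph")
}
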