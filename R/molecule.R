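# Small-molecule container: element symbols, 3D coordinates, formal charges
# and an explicit bond table. Hydrogens may be present; most scoring and RMSD
# operations work on the heavy-atom subgraph.

.ELEMENT_DATA <- local({
  d <- data.frame(
    element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si"),
    mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
                35.45, 79.904, 126.904, 10.81, 28.085),
    vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
                1.92, 2.10),
    covalent = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39,
                 0.84, 1.11),
    valence = c(1, 4, 3, 2, 2, 3, 1, 1, 1, 1, 3, 4)
  )
  rownames(d) <- d$element
  d
})

normalize_element <- function(el) {
  el <- sub("^\\s+|\\s+$", "", el)
  paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
}

element_property <- function(el, prop, default) {
  v <- .ELEMENT_DATA[normalize_element(el), prop]
  v[is.na(v)] <- default
  v
}

#' Construct a small molecule
#'
#' @param elements Character vector of element symbols.
#' @param xyz n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and numeric `order` (1, 2, 3; 4 denotes aromatic).
#' @param charges Integer formal charges per atom (default all 0).
#' @param name Optional molecule name.
#' @param smiles Optional source SMILES string.
#' @return Object of class `molecule`.
#' @export
molecule <- function(elements, xyz, bonds = NULL, charges = NULL,
                     name = NULL, smiles = NULL) {
  elements <- normalize_element(as.character(elements))
  xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  n <- length(elements)
  stopifnot(nrow(xyz) == n)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.numeric(bonds$order))
  m <- structure(list(elements = elements, xyz = xyz,
                      charges = as.integer(charges), bonds = bonds,
                      name = name, smiles = smiles),
                 class = "molecule")
  validate_molecule(m)
  m
}

validate_molecule <- function(m) {
  if (sum(m$elements != "H") < 1L)
    templig_abort("molecule must contain at least one heavy atom", "templig_empty_molecule")
  if (!all(is.finite(m$xyz)))
    templig_abort("molecule coordinates must be finite", "templig_bad_molecule")
  n <- length(m$elements)
  if (nrow(m$bonds) &&
      (min(m$bonds$i, m$bonds$j) < 1L || max(m$bonds$i, m$bonds$j) > n))
    templig_abort("bond indices out of range", "templig_bad_molecule")
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("Molecule%s: %d atoms (%d heavy), %d bonds",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$elements), n_heavy(x), nrow(x$bonds)))
  if (!is.null(x$smiles)) cat(", SMILES ", x$smiles, sep = "")
  cat("\n")
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms
#' @param mol A [molecule()].
#' @return Integer count.
#' @export
n_heavy <- function(mol) sum(mol$elements != "H")

heavy_idx <- function(mol) which(mol$elements != "H")

#' Heavy-atom coordinates
#' @param mol A [molecule()].
#' @return Matrix of heavy-atom coordinates.
#' @export
heavy_xyz <- function(mol) mol$xyz[heavy_idx(mol), , drop = FALSE]

#' Molecular weight (Da), including implicit/explicit hydrogens
#' @param mol A [molecule()].
#' @return Molecular weight in Dalton.
#' @export
mol_weight <- function(mol) {
  w <- sum(element_property(mol$elements, "mass", 12.011))
  # add implicit hydrogens where no explicit ones are present
  if (!any(mol$elements == "H")) w <- w + 1.008 * sum(implicit_h(mol))
  w
}

#' Geometric center of the heavy atoms
#' @param mol A [molecule()].
#' @return Length-3 numeric vector.
#' @export
mol_center <- function(mol) colMeans(heavy_xyz(mol))

set_coords <- function(mol, xyz) {
  mol$xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  mol
}

transform_molecule <- function(mol, tf) set_coords(mol, apply_transform(mol$xyz, tf))

# Degree and bond-order sums per atom over the full (H-included) graph.
bond_order_sum <- function(mol) {
  s <- numeric(length(mol$elements))
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + ord[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + ord[k]
    }
  }
  s
}

adjacency_list <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Implicit hydrogen count per atom from standard valences (used when the
# molecule carries no explicit hydrogens, e.g. ligands parsed from PDB).
implicit_h <- function(mol) {
  bos <- bond_order_sum(mol)
  val <- element_property(mol$elements, "valence", 4)
  pmax(0, round(val + ifelse(mol$elements == "N", mol$charges, 0) - bos))
}

# Count of hydrogens (explicit or implicit) attached to each atom.
h_count <- function(mol) {
  adj <- adjacency_list(mol)
  expl <- vapply(seq_along(adj), function(i)
    sum(mol$elements[adj[[i]]] == "H"), integer(1))
  if (any(mol$elements == "H")) expl else implicit_h(mol)
}

# Heavy-atom subgraph as an igraph object; vertex attr `element`, edge attr
# `order`. Atom indices refer to the heavy-atom sub-molecule.
mol_graph <- function(mol, heavy_only = TRUE) {
  if (heavy_only) mol <- heavy_submol(mol)
  n <- length(mol$elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  igraph::V(g)$element <- mol$elements
  if (nrow(mol$bonds)) igraph::E(g)$order <- mol$bonds$order
  g
}

# Restrict to heavy atoms, re-indexing bonds.
heavy_submol <- function(mol) {
  keep <- heavy_idx(mol)
  if (length(keep) == length(mol$elements)) return(mol)
  map <- match(seq_along(mol$elements), keep)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  molecule(mol$elements[keep], mol$xyz[keep, , drop = FALSE],
           data.frame(i = map[b$i], j = map[b$j], order = b$order),
           mol$charges[keep], mol$name, mol$smiles)
}

# Smallest rings (size 3-7) via shortest alternative path per bond.
mol_rings <- function(mol) {
  g <- mol_graph(mol)
  nb <- nrow(mol$bonds[mol$bonds$i %in% heavy_idx(mol) &
                         mol$bonds$j %in% heavy_idx(mol), , drop = FALSE])
  if (igraph::ecount(g) == 0) return(list())
  rings <- list()
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, ends[1], ends[2]))$vpath[[1]]
    if (length(sp) >= 3 && length(sp) <= 7) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = ",")
      if (!key %in% names(rings)) rings[[key]] <- as.integer(sp)
    }
  }
  unname(rings)
}

# Aromatic rings: 5-7 membered rings of C/N/O/S whose ring bonds carry either
# explicit aromatic orders (4) or an alternating Kekule pattern.
aromatic_rings <- function(mol) {
  hv <- heavy_submol(mol)
  rings <- mol_rings(hv)
  ok <- list()
  for (r in rings) {
    els <- hv$elements[r]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    inring <- hv$bonds$i %in% r & hv$bonds$j %in% r
    ord <- hv$bonds$order[inring]
    ndouble <- sum(ord == 2)
    if (any(ord == 4) || ndouble >= floor(length(r) / 2))
      ok[[length(ok) + 1]] <- r
  }
  ok
}

# Rotatable bonds of the heavy-atom graph: acyclic single bonds whose both
# ends have at least one additional heavy neighbour (terminal twists are not
# conformationally meaningful). Returns a data.frame(i, j) in heavy indices.
rotatable_bonds <- function(mol) {
  hv <- heavy_submol(mol)
  if (!nrow(hv$bonds)) return(data.frame(i = integer(), j = integer()))
  g <- mol_graph(hv)
  deg <- igraph::degree(g)
  ringset <- unique(unlist(mol_rings(hv)))
  b <- hv$bonds
  keep <- b$order == 1 &
    !(b$i %in% ringset & b$j %in% ringset & in_same_ring(hv, b)) &
    deg[b$i] >= 2 & deg[b$j] >= 2
  b[keep, c("i", "j"), drop = FALSE]
}

in_same_ring <- function(hv, b) {
  rings <- mol_rings(hv)
  vapply(seq_len(nrow(b)), function(k)
    any(vapply(rings, function(r) b$i[k] %in% r && b$j[k] %in% r, logical(1))),
    logical(1))
}

# Replace Kekule alternation by a uniform aromatic order (4) inside aromatic
# rings, so that graph matching respects the chemical ring symmetry.
normalize_aromatic_orders <- function(mol) {
  rings <- aromatic_rings(mol)
  if (!length(rings)) return(mol)
  hv_map <- heavy_idx(mol)
  for (r in rings) {
    full <- hv_map[r]
    sel <- mol$bonds$i %in% full & mol$bonds$j %in% full
    mol$bonds$order[sel] <- 4
  }
  mol
}

# Identical-graph test (same elements, same bond multiset) used to shortcut
# RMSD symmetry handling.
same_topology <- function(a, b) {
  a <- heavy_submol(a); b <- heavy_submol(b)
  length(a$elements) == length(b$elements) &&
    identical(sort(a$elements), sort(b$elements)) &&
    nrow(a$bonds) == nrow(b$bonds)
}
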