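# Symmetry-aware heavy-atom RMSD between two ligand poses, using maximum
# common substructure (MCS) atom mapping with graph-automorphism handling.
# The deviation is computed in place: no re-fitting rotation or translation
# is applied, so the value measures the pose difference in a common frame.

#' RMSD result
#'
#' @param rmsd In-place heavy-atom RMSD (Angstrom) minimized over all MCS
#'   embeddings including symmetry automorphisms.
#' @param mapping Two-column matrix of mapped atom index pairs
#'   (query, reference), heavy-atom indices.
#' @param n_query_heavy Heavy-atom count of the query molecule.
#' @return Object of class `rmsd_result` with `mcs_fraction =
#'   nrow(mapping) / n_query_heavy`.
#' @export
rmsd_result <- function(rmsd, mapping, n_query_heavy) {
  stopifnot(rmsd >= 0, nrow(mapping) >= 1)
  structure(list(rmsd = rmsd, mapping = mapping,
                 n_mapped = nrow(mapping),
                 mcs_fraction = nrow(mapping) / n_query_heavy),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("RMSD %.3f A over %d mapped atoms (MCS fraction %.2f)\n",
              x$rmsd, x$n_mapped, x$mcs_fraction))
  invisible(x)
}

# All full-graph isomorphism mappings between two heavy-atom graphs
# (element- and bond-order-constrained); empty list if not isomorphic.
full_graph_mappings <- function(a, b, cap = 5000L) {
  ga <- mol_graph(a); gb <- mol_graph(b)
  if (igraph::vcount(ga) != igraph::vcount(gb) ||
      igraph::ecount(ga) != igraph::ecount(gb)) return(list())
  lev <- sort(unique(c(a$elements, b$elements)))
  olev <- sort(unique(c(a$bonds$order, b$bonds$order, 1)))
  maps <- tryCatch(igraph::graph.get.isomorphisms.vf2(
    ga, gb,
    vertex.color1 = match(a$elements, lev),
    vertex.color2 = match(b$elements, lev),
    edge.color1 = if (igraph::ecount(ga)) match(igraph::E(ga)$order, olev) else integer(),
    edge.color2 = if (igraph::ecount(gb)) match(igraph::E(gb)$order, olev) else integer()),
    error = function(e) list())
  maps <- lapply(maps, as.integer)
  if (length(maps) > cap) maps <- maps[seq_len(cap)]
  maps
}

# Maximum common induced substructure via maximum cliques of the modular
# product (compatibility) graph. Vertices pair same-element atoms with the
# same ring-membership flag; edges require consistent adjacency and bond
# order. Returns a list of two-column mapping matrices.
mcs_mappings <- function(a, b, max_vertices = 600L, clique_cap = 2000L) {
  ga <- mol_graph(a); gb <- mol_graph(b)
  na <- igraph::vcount(ga); nb <- igraph::vcount(gb)
  ringa <- seq_len(na) %in% unlist(mol_rings(a))
  ringb <- seq_len(nb) %in% unlist(mol_rings(b))
  orda <- matrix(0, na, na); ordb <- matrix(0, nb, nb)
  if (nrow(a$bonds)) {
    orda[cbind(a$bonds$i, a$bonds$j)] <- a$bonds$order
    orda[cbind(a$bonds$j, a$bonds$i)] <- a$bonds$order
  }
  if (nrow(b$bonds)) {
    ordb[cbind(b$bonds$i, b$bonds$j)] <- b$bonds$order
    ordb[cbind(b$bonds$j, b$bonds$i)] <- b$bonds$order
  }
  pairs <- which(outer(a$elements, b$elements, "==") &
                   outer(ringa, ringb, "=="), arr.ind = TRUE)
  if (!nrow(pairs)) return(list())
  if (nrow(pairs) > max_vertices) return(mcs_greedy(a, b, orda, ordb, pairs))
  np <- nrow(pairs)
  adj <- matrix(FALSE, np, np)
  for (u in seq_len(np - 1)) {
    i <- pairs[u, 1]; j <- pairs[u, 2]
    for (v in (u + 1):np) {
      k <- pairs[v, 1]; l <- pairs[v, 2]
      if (i == k || j == l) next
      if (orda[i, k] == ordb[j, l]) adj[u, v] <- adj[v, u] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::largest_cliques(g)
  if (length(cl) > clique_cap) cl <- cl[seq_len(clique_cap)]
  lapply(cl, function(vs) pairs[as.integer(vs), , drop = FALSE])
}

# Greedy connected-extension heuristic for large compatibility graphs:
# grows a mapping from each seed pair by best-compatible extension.
mcs_greedy <- function(a, b, orda, ordb, pairs) {
  warning("MCS compatibility graph too large; using greedy heuristic mapping")
  best <- NULL
  seeds <- pairs[seq_len(min(25L, nrow(pairs))), , drop = FALSE]
  for (s in seq_len(nrow(seeds))) {
    map <- matrix(seeds[s, ], ncol = 2)
    repeat {
      ext <- NULL
      for (u in seq_len(nrow(pairs))) {
        i <- pairs[u, 1]; j <- pairs[u, 2]
        if (i %in% map[, 1] || j %in% map[, 2]) next
        ok <- all(orda[i, map[, 1]] == ordb[j, map[, 2]]) &&
          any(orda[i, map[, 1]] > 0)
        if (ok) { ext <- c(i, j); break }
      }
      if (is.null(ext)) break
      map <- rbind(map, ext)
    }
    if (is.null(best) || nrow(map) > nrow(best)) best <- map
  }
  list(best)
}

#' Symmetry-aware MCS RMSD between two ligand poses
#'
#' The minimum over all maximum-common-substructure embeddings (including
#' graph self-symmetries) of the in-place root-mean-square heavy-atom
#' deviation. When the two molecules share the full graph, all
#' element/bond-order-preserving isomorphisms are used; otherwise the MCS is
#' found by maximum cliques of the compatibility graph (ring membership
#' respected).
#'
#' @param predicted,reference [molecule()] objects with poses in the same
#'   frame; the RMSD is computed over the mapped atoms of `predicted`.
#' @param min_mcs Minimum acceptable common-substructure size (atoms).
#' @return An [rmsd_result()].
#' @export
mcs_rmsd <- function(predicted, reference, min_mcs = 3L) {
  a <- normalize_aromatic_orders(heavy_submol(predicted))
  b <- normalize_aromatic_orders(heavy_submol(reference))
  maps <- if (same_topology(a, b)) full_graph_mappings(a, b) else list()
  if (!length(maps)) {
    mm <- mcs_mappings(a, b)
    if (!length(mm) || nrow(mm[[1]]) < min_mcs)
      templig_abort(sprintf("common substructure below %d atoms", min_mcs),
                    "templig_no_common_substructure")
    best <- Inf; bestmap <- NULL
    for (m in mm) {
      r <- rmsd_xyz(a$xyz[m[, 1], , drop = FALSE], b$xyz[m[, 2], , drop = FALSE])
      if (r < best) { best <- r; bestmap <- m }
    }
    return(rmsd_result(best, bestmap, length(a$elements)))
  }
  best <- Inf; bestmap <- NULL
  for (p in maps) {
    r <- rmsd_xyz(a$xyz, b$xyz[p, , drop = FALSE])
    if (r < best) { best <- r; bestmap <- cbind(seq_along(p), p) }
  }
  rmsd_result(best, bestmap, length(a$elements))
}

#' Evaluate a pose prediction against a reference complex
#'
#' Matches the prediction's receptor onto the reference protein, applies the
#' resulting transform to the predicted ligand pose, and computes the
#' symmetry-aware MCS RMSD against the reference crystal ligand.
#'
#' @param pred A `pose_prediction` (from [predict_pose()]) or a
#'   [molecule()] pose; in the latter case supply `receptor`.
#' @param reference_complex A [complex_entry()].
#' @param receptor The receptor [protein_structure()] the pose was predicted
#'   in (taken from `pred` when it is a `pose_prediction`).
#' @return An [rmsd_result()].
#' @export
evaluate_prediction <- function(pred, reference_complex, receptor = NULL) {
  if (inherits(pred, "pose_prediction")) {
    receptor <- pred$receptor
    pose <- pred$pose
  } else pose <- pred
  stopifnot(inherits(pose, "molecule"), inherits(receptor, "protein_structure"))
  tf <- match_proteins(reference_complex$protein, receptor)
  mcs_rmsd(transform_molecule(pose, tf), reference_complex$ligand)
}
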