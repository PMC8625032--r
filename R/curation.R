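# Dataset curation: solvent-accessible surface area burial, the ordered
# discard cascade for complex entries, and per-protein grouping with
# binding-site selection and duplicate-ligand resolution.

#' Ligand SASA burial upon complex formation
#'
#' Solvent-accessible surface area is computed by deterministic numerical
#' sphere-point sampling (Shrake-Rupley; probe 1.4 Angstrom). The ligand
#' SASA is evaluated alone and in the presence of the protein; the buried
#' fraction is their difference relative to the free-ligand SASA.
#'
#' @param complex A [complex_entry()].
#' @param n_points Sphere points per atom (default 196).
#' @param probe Probe radius (Angstrom).
#' @return Object of class `burial_result` with fields `sasa_lig`,
#'   `sasa_lig_complex`, `delta_sasa`, `buried_fraction`.
#' @export
burial_fraction <- function(complex, n_points = 196L, probe = 1.4) {
  lig <- heavy_submol(complex$ligand)
  lxyz <- lig$xyz
  lrad <- element_property(lig$elements, "vdw", 1.7)
  pts <- sphere_points(n_points)
  empty <- matrix(numeric(), 0, 3)
  sasa_lig <- sum(cpp_sasa(lxyz, lrad, pts, probe, empty, numeric()))
  pa <- complex$protein$atoms
  pa <- pa[pa$element != "H", , drop = FALSE]
  prad <- element_property(pa$element, "vdw", 1.7)
  sasa_cpx <- sum(cpp_sasa(lxyz, lrad, pts, probe,
                           cbind(pa$x, pa$y, pa$z), prad))
  delta <- sasa_lig - sasa_cpx
  structure(list(sasa_lig = sasa_lig, sasa_lig_complex = sasa_cpx,
                 delta_sasa = delta,
                 buried_fraction = min(max(delta / sasa_lig, 0), 1)),
            class = "burial_result")
}

#' @export
print.burial_result <- function(x, ...) {
  cat(sprintf("SASA %.1f A^2 free, %.1f A^2 in complex: buried %.1f%%\n",
              x$sasa_lig, x$sasa_lig_complex, 100 * x$buried_fraction))
  invisible(x)
}

#' Curation thresholds
#'
#' Boundary semantics keep entries at the stated limits because the discard
#' rules are phrased strictly (fewer than 7 heavy atoms; molecular weight
#' below 140 or above 800 Da; burial below 50%). The geometric thresholds
#' for covalent linkage, pocket co-occupancy and multi-protein contact are
#' conventions of this implementation.
#'
#' @return Named list of thresholds.
#' @export
curation_defaults <- function() {
  list(covalent_dist = 1.9, pocket_dist = 8.0, multi_protein_dist = 4.0,
       min_heavy = 7L, mw_range = c(140, 800), min_burial = 0.5)
}

#' Apply the curation filter cascade to one complex entry
#'
#' Rules are tested in a fixed order and the first failure is recorded:
#' (1) ligand covalently linked to the protein; (2) another ligand in the
#' same pocket; (3) ligand contacting multiple protein entities;
#' (4) fewer than 7 heavy atoms; (5) molecular weight outside 140-800 Da;
#' then ligand burial below 50%.
#'
#' @param entry A [complex_entry()].
#' @param context Optional list with `other_ligands` (list of [molecule()])
#'   and `proteins` (list of [protein_structure()] entities in the
#'   asymmetric unit; defaults to the entry's own protein).
#' @param thresholds See [curation_defaults()].
#' @return Object of class `filter_report`: `verdict` ("keep"/"discard"),
#'   `reason`, and the measured values.
#' @export
filter_entry <- function(entry, context = list(),
                         thresholds = curation_defaults()) {
  lig <- heavy_submol(entry$ligand)
  lxyz <- lig$xyz
  pa <- entry$protein$atoms
  pa <- pa[pa$element != "H", , drop = FALSE]
  pxyz <- cbind(pa$x, pa$y, pa$z)
  nh <- n_heavy(entry$ligand)
  mw <- mol_weight(entry$ligand)
  burial <- NA_real_

  min_cross_dist <- function(A, B) {
    if (!nrow(A) || !nrow(B)) return(Inf)
    min(sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0)))
  }

  reason <- "none"
  if (min_cross_dist(lxyz, pxyz) < thresholds$covalent_dist) {
    reason <- "covalent"
  } else if (length(context$other_ligands) &&
             any(vapply(context$other_ligands, function(o)
               sqrt(sum((mol_center(o) - entry$binding_site_center)^2)) <
                 thresholds$pocket_dist, logical(1)))) {
    reason <- "multi-ligand-pocket"
  } else {
    prots <- context$proteins %||% list(entry$protein)
    ncontact <- sum(vapply(prots, function(p) {
      a <- p$atoms[p$atoms$element != "H", , drop = FALSE]
      min_cross_dist(lxyz, cbind(a$x, a$y, a$z)) < thresholds$multi_protein_dist
    }, logical(1)))
    if (ncontact >= 2) {
      reason <- "multi-protein-contact"
    } else if (nh < thresholds$min_heavy) {
      reason <- "heavy-atoms"
    } else if (mw < thresholds$mw_range[1] || mw > thresholds$mw_range[2]) {
      reason <- "molecular-weight"
    } else {
      burial <- burial_fraction(entry)$buried_fraction
      if (burial < thresholds$min_burial) reason <- "burial"
    }
  }
  structure(list(id = entry$pdb_id,
                 verdict = if (reason == "none") "keep" else "discard",
                 reason = reason, heavy_atoms = nh, mol_weight = mw,
                 buried_fraction = burial),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s: %s%s (heavy %d, MW %.1f Da%s)\n", x$id, x$verdict,
              if (x$reason == "none") "" else paste0(" [", x$reason, "]"),
              x$heavy_atoms, x$mol_weight,
              if (is.na(x$buried_fraction)) ""
              else sprintf(", buried %.0f%%", 100 * x$buried_fraction)))
  invisible(x)
}

# Single-linkage clustering of points with a distance cutoff; returns a
# cluster id per row.
single_linkage_clusters <- function(X, cutoff) {
  n <- nrow(X)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(X), method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Group curated entries into per-protein template sets
#'
#' Entries are grouped by UniProt accession (or a user-supplied key).
#' Within each protein, binding sites are clustered by single-linkage on the
#' ligand centers (8 Angstrom cutoff) and only the major site - the cluster
#' with the most co-bound ligands - is retained. Entries whose ligands share
#' a canonical SMILES are deduplicated, keeping the lowest R-free.
#'
#' @param entries List of [complex_entry()] objects.
#' @param key Optional character vector of grouping keys (defaults to the
#'   entries' `uniprot_id`).
#' @param pocket_dist Site-clustering cutoff (Angstrom).
#' @return Named list (one element per protein) of entry lists.
#' @export
group_and_select <- function(entries, key = NULL, pocket_dist = 8.0) {
  stopifnot(length(entries) >= 1)
  if (is.null(key)) key <- vapply(entries, function(e)
    as.character(e$uniprot_id), character(1))
  if (any(is.na(key) | key == "NA" | !nzchar(key)))
    templig_abort("entries without a grouping key (UniProt id)",
                  "templig_ungroupable")
  out <- list()
  for (prot in unique(key)) {
    es <- entries[key == prot]
    centers <- do.call(rbind, lapply(es, `[[`, "binding_site_center"))
    cl <- single_linkage_clusters(centers, pocket_dist)
    major <- as.integer(names(which.max(table(cl))))
    es <- es[cl == major]
    smi <- vapply(es, function(e) canonical_smiles(e$ligand), character(1))
    keep <- integer()
    for (s in unique(smi)) {
      idx <- which(smi == s)
      rf <- vapply(es[idx], function(e)
        ifelse(is.na(e$r_free), Inf, e$r_free), numeric(1))
      keep <- c(keep, idx[which.min(rf)])
    }
    out[[prot]] <- es[sort(keep)]
  }
  out
}
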