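# Deterministic synthetic fixtures: toy ligands, concave shell pockets,
# template libraries with known correct poses, and synthetic
# (similarity, RMSD) pair distributions. Everything is reproducible from a
# seed and requires no external data.

.TOY_SMILES <- c(
  "OCCOc1ccc(CC)cc1",  "NCCOc1ccc(CC)cc1",  "CCOc1ccc(CCO)cc1",
  "OCCOc1ccc(CN)cc1",  "CCCOc1ccc(CO)cc1",  "OCCSc1ccc(CC)cc1",
  "CCOc1ccccc1CCO",    "OCCNc1ccc(CC)cc1",  "CCc1ccc(OCC(C)O)cc1",
  "COc1ccc(CCN)cc1OC", "CCCCOc1ccc(CO)cc1", "OCCOc1ccccc1CC",
  "NCCOc1ccccc1OC",    "CCOc1ccc(CN)cc1C",  "OCCc1ccc(OC)cc1C",
  "CCOC1CCC(CO)CC1",   "OCCOC1CCC(CC)CC1",  "NCCOC1CCC(C)CC1",
  "OCC(O)COc1ccccc1",  "CCc1ccc(SCCO)cc1",  "COc1cccc(CCO)c1C",
  "OCCOc1ccc(F)cc1CC", "CCNc1ccc(CCO)cc1",  "OCCOc1ccc(Cl)cc1C",
  "CCOc1ccc(C(C)O)cc1", "OCCCOc1ccc(C)cc1", "CCSc1ccc(CCO)cc1",
  "COCCOc1ccc(C)cc1C", "OCCN(C)c1ccccc1C",  "CCOc1cc(C)ccc1CO")

#' Deterministic toy ligand
#'
#' Picks one of a fixed set of drug-like toy SMILES (aromatic and saturated
#' scaffolds with polar decorations, 140-200 Da) and embeds it in 3D. The
#' choice and geometry are fully determined by the seed.
#'
#' @param seed Integer seed.
#' @return A [molecule()] with 3D coordinates.
#' @export
toy_ligand <- function(seed = 1L) {
  smi <- .TOY_SMILES[(as.integer(seed) - 1L) %% length(.TOY_SMILES) + 1L]
  parse_smiles(smi, name = sprintf("toy%03d", seed))
}

# Unit icosphere directions (icosahedron subdivided `level` times).
icosphere_points <- function(level = 2L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nf <- NULL
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      mids <- integer(3)
      pairs <- list(c(a, b), c(b, cc), c(cc, a))
      for (m in 1:3) {
        mid <- (v[pairs[[m]][1], ] + v[pairs[[m]][2], ]) / 2
        hit <- which(colSums((t(v) - mid)^2) < 1e-12)
        if (length(hit)) mids[m] <- hit[1]
        else { v <- rbind(v, mid); mids[m] <- nrow(v) }
      }
      nf <- rbind(nf, c(a, mids[1], mids[3]), c(mids[1], b, mids[2]),
                  c(mids[3], mids[2], cc), mids)
    }
    f <- nf
  }
  v / sqrt(rowSums(v^2))
}

#' Build a toy pocket around a ligand pose
#'
#' A concave shell of carbon-like pseudo-atoms molded onto the ligand
#' surface: along each of a set of quasi-uniform directions (subdivided
#' icosahedron), a shell atom is placed where it first reaches van der
#' Waals contact distance plus `gap` from every ligand atom, producing a
#' snug cavity; an aperture is opened along +z to mimic the pocket mouth.
#' Every shell atom is clash-free with the seed ligand by construction.
#' The shell is returned as a single-chain poly-glycine
#' [protein_structure()] with one CA per residue so that protein matching,
#' scoring and SASA burial all operate on it.
#'
#' @param ligand A [molecule()] in its pose.
#' @param gap Clearance beyond van der Waals contact (Angstrom,
#'   default 0.9).
#' @param aperture_deg Half-angle of the opening around +z (default 90).
#' @param level Icosphere subdivision level (default 2, 162 directions).
#' @return A [protein_structure()].
#' @export
make_toy_pocket <- function(ligand, gap = 0.9, aperture_deg = 90, level = 2L) {
  center <- mol_center(ligand)
  H <- heavy_xyz(ligand)
  vdw <- element_property(heavy_submol(ligand)$elements, "vdw", 1.7)
  contact <- vdw + 1.7 + gap
  V <- sweep(H, 2, center)
  dirs <- icosphere_points(level)
  keep <- acos(pmin(pmax(dirs[, 3], -1), 1)) > aperture_deg * pi / 180
  dirs <- dirs[keep, , drop = FALSE]
  pts <- matrix(NA_real_, nrow(dirs), 3)
  fallback <- max(sqrt(rowSums(V^2))) + 3.4
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    proj <- as.numeric(V %*% d)
    perp2 <- rowSums(V^2) - proj^2
    disc <- contact^2 - perp2
    ok <- disc > 0
    r <- if (any(ok)) max(proj[ok] + sqrt(disc[ok])) else fallback
    pts[k, ] <- center + r * d
  }
  protein_structure(data.frame(
    chain = "A", resno = seq_len(nrow(pts)), resname = "GLY",
    atom_name = "CA", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3]))
}

#' Synthetic template library with known correct poses
#'
#' Builds one toy pocket around a seed ligand pose and fills it with
#' decorated scaffold variants, each superimposed into the shared binding
#' mode by 3D similarity alignment and then locally refined in the pocket so
#' that every "crystal" pose sits at a score minimum, as refined
#' experimental poses do. The query's ground-truth pose is constructed the
#' same way, so end-to-end prediction tests know the right answer.
#'
#' Profiles: `"identical"` (query equals template 1),
#' `"similar"` (query is a close analog of the templates), and
#' `"dissimilar-shared-mode"` (a saturated-scaffold query with low 2D
#' similarity to every template that nevertheless binds in the same mode -
#' the central phenomenon the intercomparison strategy measures).
#'
#' @param n_templates Number of templates (1-6).
#' @param profile Query similarity profile (see above).
#' @param seed Integer seed.
#' @return List with `library` (a [template_library()]), `query_smiles`,
#'   `truth_pose` (a [molecule()]), and `profile`.
#' @export
make_toy_library <- function(n_templates = 3L,
                             profile = c("identical", "similar",
                                         "dissimilar-shared-mode"),
                             seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(n_templates >= 1, n_templates <= 6)
  tmpl_smiles <- .TOY_SMILES[1:6][seq_len(n_templates)]
  seed_mol <- parse_smiles(tmpl_smiles[1], name = "TOY1")
  pocket <- make_toy_pocket(seed_mol)
  place <- function(smi, name) {
    m <- parse_smiles(smi, name = name)
    if (smi == tmpl_smiles[1]) posed <- m
    else posed <- transform_molecule(m, align(m, seed_mol)$transform)
    # refine to convergence so the planted "crystal" pose is a true local
    # score minimum, as refined experimental poses are
    total <- score_pose(pocket, posed)$total
    for (it in 1:4) {
      rp <- local_refine(pocket, posed)
      posed <- rp$ligand
      if (total - rp$score$total < 1e-5) break
      total <- rp$score$total
    }
    posed
  }
  entries <- vector("list", n_templates)
  for (k in seq_len(n_templates)) {
    lig <- place(tmpl_smiles[k], sprintf("TOY%d", k))
    entries[[k]] <- complex_entry(pocket, lig, pdb_id = sprintf("TOY%d", k),
                                  r_free = 0.15 + 0.01 * k,
                                  uniprot_id = "TOYPROT")
  }
  query_smiles <- switch(profile,
                         "identical" = tmpl_smiles[1],
                         "similar" = "OCCOc1ccc(C)cc1",
                         "dissimilar-shared-mode" = "OCCOC1CCC(CC)CC1")
  truth <- if (profile == "identical") entries[[1]]$ligand
  else place(query_smiles, "QUERY")
  # a seeded rigid re-orientation of the whole complex frame, so different
  # seeds exercise the pipeline in different laboratory frames
  tf <- with_seed(seed, rigid_transform(rotvec_to_mat(runif(3, -pi, pi)),
                                        runif(3, -4, 4)))
  for (k in seq_along(entries)) {
    entries[[k]]$protein <- transform_protein(entries[[k]]$protein, tf)
    entries[[k]]$ligand <- transform_molecule(entries[[k]]$ligand, tf)
    entries[[k]]$binding_site_center <- mol_center(entries[[k]]$ligand)
  }
  truth <- transform_molecule(truth, tf)
  list(library = template_library(entries, protein_id = "TOYPROT",
                                  align_frames = FALSE),
       query_smiles = query_smiles, truth_pose = truth, profile = profile,
       seed = seed)
}

#' Synthetic (similarity, RMSD) pair records
#'
#' Builds pair records whose similarity values fall in the requested bins
#' and whose RMSDs are at or below 2 Angstrom for exactly the requested
#' per-bin fraction of records (good RMSDs uniform on [0.5, 1.9], bad on
#' [3, 8]).
#'
#' @param bins List of `c(lo, hi)` similarity intervals.
#' @param per_bin_counts Integer record count per bin.
#' @param good_fractions Fraction of good (RMSD <= 2) records per bin.
#' @param seed Integer seed.
#' @return Data frame of pair records (`query`, `template`, `shafts`,
#'   `shape`, `feature`, `tanimoto`, `rmsd`, `vina`).
#' @export
make_pair_distribution <- function(bins, per_bin_counts, good_fractions,
                                   seed = 1L) {
  if (length(bins) != length(per_bin_counts) ||
      length(bins) != length(good_fractions) ||
      any(good_fractions < 0 | good_fractions > 1))
    templig_abort("bins, counts and fractions must be consistent",
                  "templig_inconsistent_spec")
  with_seed(seed, {
    rows <- list()
    for (b in seq_along(bins)) {
      n <- per_bin_counts[b]
      ngood <- round(good_fractions[b] * n)
      sh <- runif(n, bins[[b]][1], bins[[b]][2] - 1e-9)
      rmsd <- c(runif(ngood, 0.5, 1.9), runif(n - ngood, 3, 8))
      rows[[b]] <- data.frame(
        query = sprintf("q%02d_%04d", b, seq_len(n)),
        template = sprintf("t%02d_%04d", b, sample(n)),
        shafts = sh, shape = pmin(sh / 2 + 0.1, 1), feature = pmax(sh / 2 - 0.1, 0),
        tanimoto = pmin(pmax(sh / 2 + runif(n, -0.1, 0.1), 0), 1),
        rmsd = sample(rmsd), vina = NA_real_)
    }
    do.call(rbind, rows)
  })
}
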