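# Empirical protein-ligand scoring (published five-term functional form and
# weights) and local pose refinement over rigid-body plus torsional degrees
# of freedom against a rigid receptor.

# Interaction radii per element (Angstrom), united-atom convention.
.SCORE_RADII <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5,
                  Cl = 1.8, Br = 2.0, I = 2.2, H = 0)

#' Scoring-term weights
#'
#' The five distance-dependent intermolecular terms (two attractive
#' Gaussians, quadratic repulsion in the overlap region, piecewise-linear
#' hydrophobic contact and hydrogen-bond terms) use the published empirical
#' weights; the conformational entropy penalty is an additive
#' 0.05846 per rotatable bond.
#'
#' @return Named numeric vector of weights
#'   (gauss1, gauss2, repulsion, hydrophobic, hbond, torsion).
#' @export
score_weights <- function() {
  c(gauss1 = -0.035579, gauss2 = -0.005156, repulsion = 0.840245,
    hydrophobic = -0.035069, hbond = -0.587439, torsion = 0.05846)
}

ligand_atom_types <- function(mol) {
  hv <- heavy_submol(mol)
  adj <- adjacency_list(hv)
  el <- hv$elements
  hc <- h_count(mol)[heavy_idx(mol)]
  hyd <- vapply(seq_along(el), function(i)
    (el[i] == "C" && !any(el[adj[[i]]] %in% c("N", "O", "F", "S", "P"))) ||
      el[i] %in% c("Cl", "Br", "I"), logical(1))
  don <- el %in% c("N", "O") & hc >= 1
  acc <- el %in% c("N", "O") & hv$charges <= 0
  rad <- .SCORE_RADII[el]
  rad[is.na(rad)] <- 1.9
  list(rad = unname(rad), hyd = hyd, don = don, acc = acc)
}

protein_atom_types <- function(protein) {
  a <- protein$atoms[protein$atoms$element != "H", , drop = FALSE]
  el <- a$element
  r <- .SCORE_RADII[el]; r[is.na(r)] <- 1.9
  list(xyz = cbind(a$x, a$y, a$z), rad = unname(r),
       hyd = el == "C" | el %in% c("Cl", "Br", "I"),
       don = el == "N" | el == "O", acc = el == "O" | el == "N")
}

#' Pose score
#'
#' @param total Weighted sum of all terms (lower is better).
#' @param terms Named vector of unweighted term values.
#' @param weights The weight vector used.
#' @return Object of class `pose_score`.
#' @export
pose_score <- function(total, terms, weights = score_weights()) {
  stopifnot(is.finite(total), abs(total - sum(weights * terms)) < 1e-9)
  structure(list(total = total, terms = terms, weights = weights),
            class = "pose_score")
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf("Pose score: %.3f\n", x$total))
  print(round(x$terms, 4))
  invisible(x)
}

#' Score a ligand pose against a rigid protein
#'
#' Computes the five empirical intermolecular terms over heavy-atom pairs
#' within the 8 Angstrom cutoff plus the rotatable-bond penalty, and returns
#' the weighted total (kcal/mol-like, lower = better). Deterministic and
#' smooth in the coordinates; clashes are penalized by a steeply growing
#' repulsion term.
#'
#' @param protein A [protein_structure()].
#' @param ligand A [molecule()] in the pose to score.
#' @param cutoff Pair-distance cutoff (Angstrom).
#' @return A [pose_score()].
#' @export
score_pose <- function(protein, ligand, cutoff = 8.0) {
  lt <- ligand_atom_types(ligand)
  pt <- protein_atom_types(protein)
  v <- cpp_vina_terms(heavy_xyz(ligand), lt$rad, lt$hyd, lt$don, lt$acc,
                      pt$xyz, pt$rad, pt$hyd, pt$don, pt$acc, cutoff)
  terms <- c(gauss1 = v[1], gauss2 = v[2], repulsion = v[3],
             hydrophobic = v[4], hbond = v[5],
             torsion = nrow(rotatable_bonds(ligand)))
  w <- score_weights()
  pose_score(sum(w * terms), terms, w)
}

#' Refined pose
#'
#' @param ligand The refined [molecule()] pose.
#' @param score The [pose_score()] of the refined pose.
#' @param displacement Heavy-atom RMSD from the starting pose (Angstrom).
#' @return Object of class `refined_pose`.
#' @export
refined_pose <- function(ligand, score, displacement) {
  structure(list(ligand = ligand, score = score, displacement = displacement),
            class = "refined_pose")
}

#' @export
print.refined_pose <- function(x, ...) {
  cat(sprintf("Refined pose: score %.3f, displacement %.3f A\n",
              x$score$total, x$displacement))
  invisible(x)
}

#' Locally refine a ligand pose against a rigid protein
#'
#' Minimizes the empirical score over the ligand's rigid-body motion
#' (translation bounded by `max_translation`, full rotation) and its
#' rotatable torsions, keeping the protein rigid. The search runs bounded
#' quasi-Newton descent from the starting pose (optionally also from
#' deterministic single-torsion perturbations of it, via `torsion_starts`),
#' followed by simplex polishing of the best candidate to a tight fixpoint.
#' A translation-only clash-relief
#' pre-step runs when the starting pose has substantial repulsion. The
#' returned score never exceeds the starting score; if the search cannot
#' relieve a severe clash the refinement aborts.
#'
#' @param protein A [protein_structure()].
#' @param start A [molecule()] giving the starting pose.
#' @param max_translation Local-search radius for translation (Angstrom).
#' @param clash_limit Weighted repulsion above which a refined pose is
#'   declared irrecoverable.
#' @param maxit Optimizer iteration budget.
#' @param torsion_starts Torsion perturbation angles (radians) tried per
#'   rotatable bond in addition to the unperturbed start.
#' @return A [refined_pose()].
#' @export
local_refine <- function(protein, start, max_translation = 2.0,
                         clash_limit = 10.0, maxit = 250L,
                         torsion_starts = numeric()) {
  validate_molecule(start)
  pt <- protein_atom_types(protein)
  lt <- ligand_atom_types(start)
  hmap <- heavy_idx(start)
  rot <- rotatable_bonds(start)
  branches <- lapply(seq_len(nrow(rot)), function(k)
    branch_atoms(start, hmap[rot$i[k]], hmap[rot$j[k]]))
  ntor <- nrow(rot)
  w <- score_weights()
  tor_pen <- w["torsion"] * ntor
  center <- mol_center(start)
  ti <- if (ntor) hmap[rot$i] else integer()
  tj <- if (ntor) hmap[rot$j] else integer()

  pose_xyz <- function(par) cpp_pose_xyz(start$xyz, ti, tj, branches, par, center)
  terms_at <- function(par) {
    cpp_vina_terms(pose_xyz(par)[hmap, , drop = FALSE], lt$rad, lt$hyd,
                   lt$don, lt$acc, pt$xyz, pt$rad, pt$hyd, pt$don, pt$acc, 8.0)
  }
  total_at <- function(par) sum(w[1:5] * terms_at(par)) + tor_pen

  par0 <- numeric(6 + ntor)
  start_total <- total_at(par0)
  # clash-relief pre-step: translation-only descent on the repulsion term
  if (w["repulsion"] * terms_at(par0)[3] > clash_limit / 2) {
    rl <- stats::optim(numeric(3), function(p3)
      terms_at(c(p3, numeric(3 + ntor)))[3],
      method = "Nelder-Mead", control = list(maxit = 120))
    if (rl$value < terms_at(par0)[3]) par0[1:3] <- rl$par
  }
  if (!is.finite(total_at(par0)))
    templig_abort("starting pose score is not finite after clash relief",
                  "templig_irrecoverable_clash")

  lower <- c(rep(-max_translation, 3), rep(-pi, 3), rep(-2 * pi, ntor))
  upper <- c(rep(max_translation, 3), rep(pi, 3), rep(2 * pi, ntor))
  descend <- function(par) {
    opt <- tryCatch(
      stats::optim(par, total_at, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) list(par = par, value = total_at(par)) else opt
  }
  starts <- list(par0)
  if (ntor) for (k in seq_len(ntor)) for (dtheta in torsion_starts) {
    p <- par0
    p[6 + k] <- p[6 + k] + dtheta
    starts[[length(starts) + 1]] <- p
  }
  best <- list(par = par0, val = start_total)
  for (p in starts) {
    opt <- descend(p)
    if (opt$value < best$val) best <- list(par = opt$par, val = opt$value)
  }
  # simplex polish of the winner to a tight fixpoint
  for (cycle in 1:3) {
    nm <- stats::optim(best$par, total_at, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    nm$par <- pmin(pmax(nm$par, lower), upper)   # keep within the search box
    nm$value <- total_at(nm$par)
    gain <- best$val - nm$value
    if (nm$value < best$val) best <- list(par = nm$par, val = nm$value)
    opt <- descend(best$par)
    if (opt$value < best$val) {
      gain <- max(gain, best$val - opt$value)
      best <- list(par = opt$par, val = opt$value)
    }
    if (gain < 1e-6) break
  }
  final_terms <- c(terms_at(best$par), ntor)
  names(final_terms) <- names(w)
  if (w["repulsion"] * final_terms["repulsion"] > clash_limit)
    templig_abort("severe steric clash could not be relieved locally",
                  "templig_irrecoverable_clash")
  xyz <- pose_xyz(best$par)
  refined_pose(set_coords(start, xyz),
               pose_score(sum(w * final_terms), final_terms, w),
               rmsd_xyz(xyz[hmap, , drop = FALSE], heavy_xyz(start)))
}
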