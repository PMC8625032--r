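# The three-step template-guiding prediction: conformer superimposition onto
# each template ligand, local refinement against that template's receptor,
# and re-ranking with the hybrid score
#   Hybrid = Vina-like binding score + alpha * 3D similarity,
# where alpha = min(binding scores)/2 for the protein, so that the two
# contributions have comparable magnitude (the similarity is at most 2).

#' Template library for one protein
#'
#' All member complexes are matched into the frame of the first (reference)
#' entry by protein superposition; ligand poses are transformed accordingly.
#'
#' @param entries List of [complex_entry()] objects for one protein.
#' @param protein_id Identifier for the protein.
#' @param align_frames Superpose all entries onto the first (default TRUE;
#'   set FALSE when the entries are already in one frame).
#' @return Object of class `template_library`.
#' @export
template_library <- function(entries, protein_id = "protein",
                             align_frames = TRUE) {
  stopifnot(length(entries) >= 1)
  if (align_frames && length(entries) > 1) {
    ref <- entries[[1]]$protein
    for (k in seq_along(entries)[-1]) {
      tf <- match_proteins(ref, entries[[k]]$protein)
      entries[[k]]$protein <- transform_protein(entries[[k]]$protein, tf)
      entries[[k]]$ligand <- transform_molecule(entries[[k]]$ligand, tf)
      entries[[k]]$binding_site_center <- mol_center(entries[[k]]$ligand)
    }
  }
  structure(list(protein_id = protein_id, entries = entries, alpha = NA_real_),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("Template library '%s': %d template(s)%s\n", x$protein_id,
              length(x$entries),
              if (is.na(x$alpha)) "" else sprintf(", alpha = %.3f", x$alpha)))
  invisible(x)
}

#' @export
length.template_library <- function(x) length(x$entries)

#' Similarity-weighting constant for the hybrid score
#'
#' `alpha = min(binding scores) / 2`. With negative (favourable) binding
#' scores alpha is negative, so a larger 3D similarity lowers (improves) the
#' hybrid score, and because the similarity is bounded by 2 the similarity
#' contribution is commensurate with the best binding score.
#'
#' @param vina_scores Numeric vector of binding scores.
#' @return `min(vina_scores) / 2`.
#' @export
compute_alpha <- function(vina_scores) {
  if (!length(vina_scores))
    templig_abort("cannot compute alpha from an empty score list",
                  "templig_empty_scores")
  min(vina_scores) / 2
}

#' Pose prediction record
#'
#' @param query_id,template_id Identifiers.
#' @param pose Refined [molecule()] pose.
#' @param vina_score Binding score of the refined pose.
#' @param shafts_score Hybrid 3D similarity (in `[0, 2]`) of the
#'   superimposition that produced the pose.
#' @param alpha The library constant used.
#' @param receptor The template's receptor the pose was refined against.
#' @return Object of class `pose_prediction` with
#'   `hybrid_score = vina_score + alpha * shafts_score` and `rank` `NA`
#'   until ranked.
#' @export
pose_prediction <- function(query_id, template_id, pose, vina_score,
                            shafts_score, alpha, receptor = NULL) {
  structure(list(query_id = query_id, template_id = template_id, pose = pose,
                 vina_score = vina_score, shafts_score = shafts_score,
                 alpha = alpha,
                 hybrid_score = vina_score + alpha * shafts_score,
                 rank = NA_integer_, receptor = receptor),
            class = "pose_prediction")
}

#' @export
print.pose_prediction <- function(x, ...) {
  cat(sprintf(
    "Prediction %s <- template %s: vina %.3f, similarity %.3f, hybrid %.3f%s\n",
    x$query_id, x$template_id, x$vina_score, x$shafts_score, x$hybrid_score,
    if (is.na(x$rank)) "" else sprintf(" (rank %d)", x$rank)))
  invisible(x)
}

#' Predict the binding mode of a query ligand from a template library
#'
#' For each template: the query's conformer ensemble is rigidly superimposed
#' onto the template ligand by hybrid 3D similarity, the best conformer is
#' locally refined against that template's receptor, and the refined pose is
#' scored. The candidate poses are then re-ranked by the hybrid score (with
#' `alpha = min(binding scores)/2` over this run); rank 1 is the method's
#' answer. Ties are broken by lower binding score, then higher similarity,
#' then template order.
#'
#' @param query_smiles SMILES of the query ligand.
#' @param library A [template_library()].
#' @param max_conformers Conformer ensemble cap (default 200).
#' @param seed Integer seed for conformer generation.
#' @param query_id Identifier for the query.
#' @param ... Passed to [generate_conformers()].
#' @return List of `pose_prediction` objects sorted by increasing hybrid
#'   score (class `pose_prediction_list`).
#' @export
predict_pose <- function(query_smiles, library, max_conformers = 200L,
                         seed = 1L, query_id = "query", ...) {
  stopifnot(inherits(library, "template_library"))
  if (!length(library$entries))
    templig_abort("template library is empty", "templig_no_prediction")
  confs <- generate_conformers(query_smiles, max_count = max_conformers,
                               seed = seed, ...)
  preds <- list()
  for (k in seq_along(library$entries)) {
    entry <- library$entries[[k]]
    cand <- tryCatch({
      al <- best_superimposition(confs, entry$ligand)
      posed <- transform_molecule(conformer_molecule(confs, al$query_conformer_index),
                                  al$transform)
      ref <- local_refine(entry$protein, posed)
      list(al = al, ref = ref)
    }, templig_error = function(e) NULL)
    if (is.null(cand)) next
    preds[[length(preds) + 1]] <- pose_prediction(
      query_id, entry$pdb_id, cand$ref$ligand, cand$ref$score$total,
      cand$al$hybrid_sim, alpha = NA_real_, receptor = entry$protein)
  }
  if (!length(preds))
    templig_abort("no template produced a refined pose", "templig_no_prediction")
  rank_predictions(preds)
}

# Re-scoring and ranking: alpha = min(vina)/2 over this run's candidates,
# hybrid = vina + alpha * similarity, ascending sort with deterministic
# tie-breaks (lower vina, higher similarity, template id).
rank_predictions <- function(preds) {
  alpha <- compute_alpha(vapply(preds, `[[`, numeric(1), "vina_score"))
  for (k in seq_along(preds)) {
    preds[[k]]$alpha <- alpha
    preds[[k]]$hybrid_score <- preds[[k]]$vina_score +
      alpha * preds[[k]]$shafts_score
  }
  ord <- order(vapply(preds, `[[`, numeric(1), "hybrid_score"),
               vapply(preds, `[[`, numeric(1), "vina_score"),
               -vapply(preds, `[[`, numeric(1), "shafts_score"),
               vapply(preds, `[[`, character(1), "template_id"))
  preds <- preds[ord]
  for (k in seq_along(preds)) preds[[k]]$rank <- k
  structure(preds, class = "pose_prediction_list")
}

#' @export
print.pose_prediction_list <- function(x, ...) {
  cat(sprintf("Pose predictions (%d candidates):\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' Binding-site distance filter
#'
#' A predicted pose is kept only when the distance between its geometric
#' center and the reference binding-site center is at most 10 Angstrom
#' (strictly larger distances are discarded).
#'
#' @param predicted_center,reference_center Length-3 centers (Angstrom), or
#'   objects with centers ([molecule()] / [complex_entry()]).
#' @param cutoff Distance cutoff (Angstrom).
#' @return `"keep"` or `"discard"`.
#' @export
site_check <- function(predicted_center, reference_center, cutoff = 10.0) {
  cen <- function(x) {
    if (inherits(x, "molecule")) return(mol_center(x))
    if (inherits(x, "complex_entry")) return(x$binding_site_center)
    as.numeric(x)
  }
  d <- sqrt(sum((cen(predicted_center) - cen(reference_center))^2))
  if (d > cutoff) "discard" else "keep"
}

#' Success rate of binding-mode predictions
#'
#' A prediction counts as a success when its top-ranked pose RMSD is
#' strictly below the threshold.
#'
#' @param rmsds Numeric vector of top-rank RMSDs (Angstrom).
#' @param threshold Success threshold (Angstrom, default 2.0).
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(rmsds, threshold = 2.0) {
  if (!length(rmsds))
    templig_abort("empty RMSD list", "templig_empty_results")
  100 * sum(rmsds < threshold) / length(rmsds)
}
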