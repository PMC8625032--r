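# Statistical analyses: all-versus-all intercomparison of a template
# library, RMSD-versus-similarity summaries, coverage curves, and the nested
# bootstrap estimating the minimum number of templates needed to include at
# least one good binding mode.

#' All-versus-all intercomparison of a template library
#'
#' Every ordered (query, template) pair of distinct library members is
#' processed with the intercomparison strategy: conformers of the query
#' ligand are generated from its SMILES, superimposed onto the template's
#' crystal pose by hybrid 3D similarity, and the best-superimposed conformer
#' is compared against the query's own crystal pose by symmetry-aware RMSD.
#' A library of N members yields exactly N*(N-1) records. The RMSD is
#' computed on the query molecule, so swapping query and template generally
#' changes the value.
#'
#' @param library A [template_library()] (members in one frame).
#' @param seed Integer seed for conformer generation.
#' @param max_conformers Conformer cap per query (default 200).
#' @param refine Also locally refine the best pose against the template's
#'   receptor and record the binding score (default FALSE).
#' @return Data frame of pair records: `query`, `template`, `shafts`,
#'   `shape`, `feature`, `tanimoto`, `rmsd`, `vina`.
#' @export
intercompare_all <- function(library, seed = 1L, max_conformers = 200L,
                             refine = FALSE) {
  stopifnot(inherits(library, "template_library"))
  n <- length(library$entries)
  if (n < 2)
    templig_abort("intercomparison needs at least two library members",
                  "templig_insufficient_library")
  ids <- vapply(library$entries, `[[`, character(1), "pdb_id")
  confs <- lapply(seq_len(n), function(k) {
    smi <- library$entries[[k]]$ligand$smiles %||%
      canonical_smiles(library$entries[[k]]$ligand)
    generate_conformers(smi, max_count = max_conformers, seed = seed + k)
  })
  rows <- list()
  for (q in seq_len(n)) for (t in seq_len(n)) {
    if (q == t) next
    qe <- library$entries[[q]]; te <- library$entries[[t]]
    al <- best_superimposition(confs[[q]], te$ligand)
    posed <- transform_molecule(
      conformer_molecule(confs[[q]], al$query_conformer_index), al$transform)
    vina <- NA_real_
    if (refine) {
      rp <- tryCatch(local_refine(te$protein, posed),
                     templig_error = function(e) NULL)
      if (!is.null(rp)) { posed <- rp$ligand; vina <- rp$score$total }
    }
    rmsd <- mcs_rmsd(posed, qe$ligand)$rmsd
    rows[[length(rows) + 1]] <- data.frame(
      query = ids[q], template = ids[t], shafts = al$hybrid_sim,
      shape = al$shape_score, feature = al$feature_score,
      tanimoto = tanimoto2d(qe$ligand, te$ligand), rmsd = rmsd, vina = vina)
  }
  do.call(rbind, rows)
}

#' Coverage curve: queries with at least one good template
#'
#' For each query the minimum RMSD over its templates (within a similarity
#' stratum) is taken; the curve reports, per threshold, the percentage of
#' queries whose minimum is at or below it. Strata are "similar" (hybrid 3D
#' similarity at or above the cutoff) and "dissimilar"; a stratum with no
#' templates for any query is reported as `NA`, not 0.
#'
#' @param records Pair-record data frame from [intercompare_all()].
#' @param thresholds RMSD thresholds (Angstrom).
#' @param similar_cutoff Similarity cutoff (default 1.2).
#' @return Data frame with columns `threshold`, `stratum`, `n_queries`,
#'   `coverage` (percent).
#' @export
coverage_curve <- function(records, thresholds = c(1, 2, 3),
                           similar_cutoff = 1.2) {
  stopifnot(nrow(records) >= 1)
  strata <- list(similar = records$shafts >= similar_cutoff,
                 dissimilar = records$shafts < similar_cutoff)
  out <- list()
  for (s in names(strata)) {
    sub <- records[strata[[s]], , drop = FALSE]
    mins <- if (nrow(sub)) tapply(sub$rmsd, sub$query, min) else numeric()
    for (th in thresholds) {
      cov <- if (length(mins)) 100 * mean(mins <= th) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        threshold = th, stratum = s, n_queries = length(mins), coverage = cov)
    }
  }
  do.call(rbind, out)
}

#' Bootstrap result
#'
#' @param n_min Mean minimum template count over the outer replicates.
#' @param n_min_se Standard error of that mean.
#' @param n_min_values The individual outer-replicate values.
#' @param inner,outer Replicate counts used.
#' @return Object of class `bootstrap_result`.
#' @export
bootstrap_result <- function(n_min, n_min_se, n_min_values, inner, outer) {
  stopifnot(n_min >= 1, n_min_se >= 0)
  structure(list(n_min = n_min, n_min_se = n_min_se,
                 n_min_values = n_min_values, inner = inner, outer = outer),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("N_min = %.2f +/- %.2f (inner %d, outer %d)\n",
              x$n_min, x$n_min_se, x$inner, x$outer))
  invisible(x)
}

#' Minimum number of templates covering a good binding mode
#'
#' Nested bootstrap over the RMSD values of one similarity bin: in the inner
#' loop, n records are drawn without replacement and the minimum RMSD kept;
#' over 500 such draws the mean and standard error of the minimum are
#' computed, and n grows from 1 until mean + SE is no higher than the
#' good-mode threshold (2.0 Angstrom). The resulting N_min is re-estimated
#' in 100 outer replicates whose mean and standard error are reported.
#'
#' @param rmsds RMSD values (Angstrom) of the records in one similarity bin.
#' @param rmsd_good Good-mode threshold (default 2.0).
#' @param inner,outer Replicate counts (defaults 500 and 100).
#' @param seed Integer seed; outer replicate i uses `seed + i`.
#' @param min_records Minimum bin occupancy (default 100; smaller bins carry
#'   too little information for the estimate).
#' @return A [bootstrap_result()].
#' @export
min_templates_bootstrap <- function(rmsds, rmsd_good = 2.0, inner = 500L,
                                    outer = 100L, seed = 1L,
                                    min_records = 100L) {
  rmsds <- as.numeric(rmsds)
  N <- length(rmsds)
  if (N < min_records)
    templig_abort(sprintf("bin holds %d records; at least %d required", N,
                          min_records), "templig_insufficient_bin")
  if (!any(rmsds <= rmsd_good))
    templig_abort("bin contains no good binding mode at the threshold",
                  "templig_unreachable")
  one_rep <- function(rep_seed) {
    with_seed(rep_seed, {
      for (n in seq_len(N)) {
        mins <- vapply(seq_len(inner), function(i) min(sample(rmsds, n)),
                       numeric(1))
        if (mean(mins) + sd(mins) / sqrt(inner) <= rmsd_good) return(n)
      }
      NA_integer_
    })
  }
  vals <- vapply(seq_len(outer), function(i) one_rep(seed + i), numeric(1))
  if (anyNA(vals))
    templig_abort("criterion not reachable within the bin size",
                  "templig_unreachable")
  bootstrap_result(mean(vals), sd(vals) / sqrt(outer), vals, inner, outer)
}

#' Shafts-score bin edges used for binned summaries
#'
#' Half-open bins of width 0.1 on `[0.8, 1.6)` with open-ended tails below
#' 0.8 and at or above 1.6.
#'
#' @return Data frame with `lo`, `hi`, `label`.
#' @export
shafts_bins <- function() {
  lo <- c(-Inf, seq(0.8, 1.5, by = 0.1), 1.6)
  hi <- c(0.8, seq(0.9, 1.6, by = 0.1), Inf)
  data.frame(lo = lo, hi = hi,
             label = c("<0.8", sprintf("[%.1f,%.1f)", lo[2:9], hi[2:9]),
                       ">=1.6"))
}

#' Binned good-mode fractions and metric-RMSD correlation
#'
#' Splits the records into half-open bins of the chosen similarity metric
#' (width 0.1) and reports, per bin, the fraction of records with RMSD at or
#' below the good-mode threshold. Bins with fewer than `min_bin` records are
#' flagged insufficient and their fraction reported as `NA`. The Pearson
#' correlation between the metric and the RMSD over all records is attached
#' as attribute `"pearson_r"` (`NA` when degenerate).
#'
#' @param records Pair-record data frame.
#' @param metric One of `"shafts"`, `"shape"`, `"feature"`, `"tanimoto"`.
#' @param bin_width Bin width (default 0.1).
#' @param rmsd_good Good-mode RMSD threshold (default 2.0).
#' @param min_bin Minimum records per bin (default 100).
#' @return Data frame with `bin_lo`, `bin_hi`, `n`, `frac_good`,
#'   `insufficient`; attribute `pearson_r`.
#' @export
binned_stats <- function(records, metric = c("shafts", "shape", "feature",
                                             "tanimoto"),
                         bin_width = 0.1, rmsd_good = 2.0, min_bin = 100L) {
  metric <- match.arg(metric)
  stopifnot(nrow(records) >= 1)
  x <- records[[metric]]
  lo0 <- floor(min(x) / bin_width) * bin_width
  edges <- seq(lo0, max(x) + bin_width, by = bin_width)
  idx <- findInterval(x, edges, rightmost.closed = FALSE)
  out <- list()
  for (b in sort(unique(idx))) {
    sel <- idx == b
    nb <- sum(sel)
    out[[length(out) + 1]] <- data.frame(
      bin_lo = edges[b], bin_hi = edges[b] + bin_width, n = nb,
      frac_good = if (nb >= min_bin) mean(records$rmsd[sel] <= rmsd_good)
      else NA_real_,
      insufficient = nb < min_bin)
  }
  res <- do.call(rbind, out)
  r <- if (sd(x) > 0 && sd(records$rmsd) > 0)
    cor(x, records$rmsd) else NA_real_
  attr(res, "pearson_r") <- r
  res
}
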