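# Hybrid 3D similarity: Gaussian shape overlap plus pharmacophore feature
# matching, with a deterministic multi-start rigid alignment optimizer, and
# 2D path-fingerprint Tanimoto similarity.

.GAUSS_P <- 2.7   # Gaussian amplitude convention; alpha reproduces vdW volume

gauss_alpha <- function(elements) {
  r <- element_property(elements, "vdw", 1.70)
  pi * (3 * .GAUSS_P / (4 * pi * r^3))^(2 / 3)
}

#' Gaussian shape overlap volume between two molecules
#'
#' Heavy atoms are modelled as spherical Gaussians whose integral equals the
#' atomic van der Waals volume; the overlap is the first-order (pairwise)
#' product integral, in cubic Angstrom. Symmetric in its arguments.
#'
#' @param molA,molB [molecule()] objects (poses are taken as-is).
#' @return Overlap volume (numeric scalar).
#' @export
gaussian_shape_overlap <- function(molA, molB) {
  A <- heavy_xyz(molA); B <- heavy_xyz(molB)
  cpp_gauss_overlap(A, gauss_alpha(heavy_submol(molA)$elements),
                    B, gauss_alpha(heavy_submol(molB)$elements), .GAUSS_P)
}

.FEATURE_KINDS <- c("donor", "acceptor", "hydrophobe", "aromatic",
                    "positive", "negative")

#' Perceive pharmacophore features of a molecule
#'
#' Rule-based perception on the heavy-atom graph: N/O with an attached
#' (explicit or implied) hydrogen are donors; neutral or anionic N/O are
#' acceptors; carbons with no bond to a heteroatom are hydrophobes; each
#' aromatic ring contributes one feature at its centroid; atoms with nonzero
#' formal charge give charge-center features.
#'
#' @param mol A [molecule()].
#' @return Data frame with columns `kind`, `x`, `y`, `z`, `radius` (Angstrom
#'   tolerance radius). May have zero rows.
#' @export
perceive_features <- function(mol) {
  hv <- heavy_submol(mol)
  hc <- h_count(mol)[heavy_idx(mol)]
  adj <- adjacency_list(hv)
  el <- hv$elements
  feats <- list()
  add <- function(kind, xyz, radius = 1.0)
    feats[[length(feats) + 1]] <<- data.frame(
      kind = kind, x = xyz[1], y = xyz[2], z = xyz[3], radius = radius)
  for (i in seq_along(el)) {
    if (el[i] %in% c("N", "O")) {
      if (hc[i] >= 1) add("donor", hv$xyz[i, ])
      if (hv$charges[i] <= 0) add("acceptor", hv$xyz[i, ])
    }
    if (el[i] == "C") {
      nbr <- el[adj[[i]]]
      if (!any(nbr %in% c("N", "O", "F", "S", "P", "Cl", "Br")) &&
          hv$charges[i] == 0)
        add("hydrophobe", hv$xyz[i, ])
    }
    if (hv$charges[i] > 0) add("positive", hv$xyz[i, ])
    if (hv$charges[i] < 0) add("negative", hv$xyz[i, ])
  }
  for (r in aromatic_rings(mol))
    add("aromatic", colMeans(hv$xyz[r, , drop = FALSE]))
  if (!length(feats))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric()))
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

feature_kernel_sum <- function(FA, FB, sigma = 1.0) {
  if (!nrow(FA) || !nrow(FB)) return(0)
  cpp_feature_sum(as.matrix(FA[, c("x", "y", "z")]),
                  match(FA$kind, .FEATURE_KINDS),
                  as.matrix(FB[, c("x", "y", "z")]),
                  match(FB$kind, .FEATURE_KINDS), sigma)
}

#' Alignment result
#'
#' @param transform [rigid_transform()] applied to the query conformer.
#' @param shape_score,feature_score Components in `[0, 1]`.
#' @param query_conformer_index Index of the aligned conformer (or `NA`).
#' @return Object of class `alignment_result` with `hybrid_sim =
#'   shape_score + feature_score` in `[0, 2]`.
#' @export
alignment_result <- function(transform, shape_score, feature_score,
                             query_conformer_index = NA_integer_) {
  stopifnot(shape_score >= -1e-9, shape_score <= 1 + 1e-9,
            feature_score >= -1e-9, feature_score <= 1 + 1e-9)
  structure(list(transform = transform,
                 shape_score = min(max(shape_score, 0), 1),
                 feature_score = min(max(feature_score, 0), 1),
                 hybrid_sim = min(max(shape_score, 0), 1) +
                   min(max(feature_score, 0), 1),
                 query_conformer_index = as.integer(query_conformer_index)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "Alignment: hybrid %.3f (shape %.3f + feature %.3f)%s\n",
    x$hybrid_sim, x$shape_score, x$feature_score,
    if (is.na(x$query_conformer_index)) ""
    else sprintf(", conformer %d", x$query_conformer_index)))
  invisible(x)
}

# Principal-axes frame with a deterministic sign convention: axes ordered by
# decreasing variance, signs fixed so the skewness along each axis is >= 0,
# handedness corrected on the last axis.
principal_frame <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  e <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  V <- e$vectors
  for (k in 1:3) {
    s <- sum((Xc %*% V[, k])^3)
    if (abs(s) < 1e-9) s <- sum(Xc %*% V[, k] >= 0) - nrow(Xc) / 2
    if (s < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# 12 deterministic starting rotations in canonical principal-axes space:
# 180-degree flips about each axis composed with cyclic axis permutations.
start_rotations <- function() {
  flips <- list(diag(3),
                diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  perms <- list(diag(3),
                matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3),
                matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3))
  out <- list()
  for (p in perms) for (f in flips) out[[length(out) + 1]] <- f %*% p
  out
}

#' Rigidly align a query conformer onto a template ligand
#'
#' Maximizes the hybrid 3D similarity (shape overlap + pharmacophore match)
#' over rigid motions of the query, using deterministic multi-start local
#' optimization: 12 principal-axes starting orientations are screened, and
#' the best few are refined with a derivative-free simplex search. Scores
#' are normalized so a molecule aligned onto itself scores shape 1,
#' feature 1, hybrid 2.
#'
#' @param query A [molecule()] (the conformer to move).
#' @param template A [molecule()] in its fixed pose.
#' @param sigma Feature match Gaussian width (Angstrom, default 1.0).
#' @param refine_top Number of screened starts refined locally.
#' @param maxit Simplex iterations per refined start.
#' @return An [alignment_result()]; `transform` maps the query's input
#'   coordinates onto the template.
#' @export
align <- function(query, template, sigma = 1.0, refine_top = 4L, maxit = 200L) {
  qh <- heavy_submol(query); th <- heavy_submol(template)
  A <- qh$xyz; B <- th$xyz
  alA <- gauss_alpha(qh$elements); alB <- gauss_alpha(th$elements)
  FA <- perceive_features(query); FB <- perceive_features(template)
  FAxyz <- as.matrix(FA[, c("x", "y", "z")])
  FAkind <- match(FA$kind, .FEATURE_KINDS)
  FBxyz <- as.matrix(FB[, c("x", "y", "z")])
  FBkind <- match(FB$kind, .FEATURE_KINDS)
  O_AA <- cpp_gauss_overlap(A, alA, A, alA, .GAUSS_P)
  O_BB <- cpp_gauss_overlap(B, alB, B, alB, .GAUSS_P)
  S_AA <- if (nrow(FA)) cpp_feature_sum(FAxyz, FAkind, FAxyz, FAkind, sigma) else 0
  S_BB <- if (nrow(FB)) cpp_feature_sum(FBxyz, FBkind, FBxyz, FBkind, sigma) else 0
  o_norm <- max(O_AA, O_BB)
  s_norm <- max(S_AA, S_BB)

  # work in each molecule's canonical principal-axes frame: the optimization
  # then sees identical inputs whatever laboratory frame the poses are in,
  # so the result is exactly rigid-invariant
  cA <- colMeans(A); cB <- colMeans(B)
  VA <- principal_frame(A); VB <- principal_frame(B)
  Ac <- sweep(A, 2, cA) %*% VA
  Bc <- sweep(B, 2, cB) %*% VB
  Fc <- if (nrow(FA)) sweep(FAxyz, 2, cA) %*% VA else FAxyz
  FBc <- if (nrow(FB)) sweep(FBxyz, 2, cB) %*% VB else FBxyz

  score_par <- function(R0, par) {
    R <- rotvec_to_mat(par[4:6]) %*% R0
    Ax <- sweep(Ac %*% t(R), 2, -par[1:3])
    sh <- cpp_gauss_overlap(Ax, alA, Bc, alB, .GAUSS_P) / o_norm
    fe <- if (s_norm > 0 && nrow(FA)) {
      Fx <- sweep(Fc %*% t(R), 2, -par[1:3])
      cpp_feature_sum(Fx, FAkind, FBc, FBkind, sigma) / s_norm
    } else 0
    c(shape = min(sh, 1), feature = min(fe, 1))
  }

  starts <- start_rotations()
  init <- vapply(starts, function(R0) sum(score_par(R0, numeric(6))),
                 numeric(1))
  best <- list(val = -Inf, R = NULL, comp = NULL, par = NULL)
  for (k in order(-init)[seq_len(min(refine_top, length(starts)))]) {
    R0 <- starts[[k]]
    obj <- function(par) -sum(score_par(R0, par))
    opt <- stats::optim(numeric(6), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    par <- if (-opt$value >= init[k]) opt$par else numeric(6)
    comp <- score_par(R0, par)
    if (sum(comp) > best$val)
      best <- list(val = sum(comp), R = rotvec_to_mat(par[4:6]) %*% R0,
                   comp = comp, par = par)
  }
  # map the canonical-space solution back to the laboratory frames
  R_lab <- VB %*% best$R %*% t(VA)
  t_lab <- as.numeric(VB %*% best$par[1:3] + cB - R_lab %*% cA)
  alignment_result(rigid_transform(R_lab, t_lab),
                   best$comp["shape"], best$comp["feature"])
}

#' Best superimposition of a conformer ensemble onto a template
#'
#' Aligns every conformer and returns the one with the highest hybrid
#' similarity; ties are broken by the lower conformer index.
#'
#' @param confs A [conformer_set()].
#' @param template A [molecule()] in its fixed pose.
#' @param ... Passed to [align()].
#' @return An [alignment_result()] with `query_conformer_index` set.
#' @export
best_superimposition <- function(confs, template, ...) {
  stopifnot(inherits(confs, "conformer_set"), length(confs$conformers) >= 1)
  best <- NULL
  for (k in seq_along(confs$conformers)) {
    m <- conformer_molecule(confs, k)
    al <- align(m, template, ...)
    al$query_conformer_index <- k
    if (is.null(best) || al$hybrid_sim > best$hybrid_sim + 1e-12) best <- al
  }
  best
}

# ---- 2D fingerprints -------------------------------------------------------

# Hashed linear-path fingerprint: all simple paths of 1..max_len heavy atoms,
# encoded as element/bond-order strings (canonicalized over direction) and
# hashed into nbits buckets.
path_fingerprint <- function(mol, max_len = 7L, nbits = 2048L) {
  hv <- heavy_submol(mol)
  adj <- adjacency_list(hv)
  ord <- matrix(0, length(hv$elements), length(hv$elements))
  if (nrow(hv$bonds)) {
    ord[cbind(hv$bonds$i, hv$bonds$j)] <- hv$bonds$order
    ord[cbind(hv$bonds$j, hv$bonds$i)] <- hv$bonds$order
  }
  paths <- character()
  walk <- function(path) {
    n <- length(path)
    key_f <- path_key(path, hv$elements, ord)
    key_r <- path_key(rev(path), hv$elements, ord)
    paths[[length(paths) + 1]] <<- if (key_f < key_r) key_f else key_r
    if (n >= max_len) return()
    for (nb in adj[[path[n]]]) if (!nb %in% path) walk(c(path, nb))
  }
  for (i in seq_along(hv$elements)) walk(i)
  unique(vapply(unique(paths), str_hash, numeric(1), nbits = nbits))
}

path_key <- function(path, el, ord) {
  n <- length(path)
  if (n == 1) return(el[path])
  parts <- character(2 * n - 1)
  parts[seq(1, 2 * n - 1, 2)] <- el[path]
  parts[seq(2, 2 * n - 2, 2)] <- ord[cbind(path[-n], path[-1])]
  paste(parts, collapse = "")
}

str_hash <- function(s, nbits) {
  h <- 5381
  for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
  h %% nbits
}

#' 2D Tanimoto similarity of two molecules
#'
#' Computed on hashed linear-path fingerprints (2048 bits, paths up to 7
#' atoms): `|A & B| / |A | B|` over the set bits. Identical graphs score 1.
#'
#' @param molA,molB [molecule()] objects.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto2d <- function(molA, molB) {
  a <- path_fingerprint(molA)
  b <- path_fingerprint(molB)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
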