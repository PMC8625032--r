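# Internal helpers: classed conditions, rigid-body geometry, seeded RNG.

templig_abort <- function(message, class) {
  stop(structure(
    class = c(class, "templig_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Rigid-body transform
#'
#' A proper rotation (3x3, det = +1) plus a translation vector, applied as
#' `x %*% t(rotation) + translation` to row-vector coordinates in Angstrom.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 vector (Angstrom).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    templig_abort("rotation matrix is not orthonormal", "templig_bad_transform")
  if (det(rotation) < 0)
    templig_abort("rotation matrix must be proper (det = +1)", "templig_bad_transform")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 4))
  cat("  translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param tf A [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tf$rotation), 2, -tf$translation)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

# Rotation matrix from a rotation vector (axis * angle, radians).
rotvec_to_mat <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Least-squares superposition (Kabsch): returns the rigid transform mapping P
# onto Q (both n x 3) minimizing the RMSD of corresponding rows.
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, as.numeric(cq - R %*% cp))
}

rmsd_xyz <- function(A, B) sqrt(mean(rowSums((as.matrix(A) - as.matrix(B))^2)))

# Best-fit RMSD after optimal superposition.
fitted_rmsd <- function(A, B) {
  tf <- kabsch(A, B)
  rmsd_xyz(apply_transform(A, tf), B)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
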