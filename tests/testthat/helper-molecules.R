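# Hand-built tiny molecules with known coordinates (no embedding needed),
# plus lazily cached shared fixtures so expensive constructions run once.

mk_methane <- function() {
  molecule("C", matrix(0, 1, 3), name = "methane")
}

# Ethanol heavy skeleton C-C-O with implicit hydrogens.
mk_ethanol <- function() {
  molecule(c("C", "C", "O"),
           rbind(c(0, 0, 0), c(1.51, 0, 0), c(2.0, 1.33, 0)),
           data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)),
           name = "ethanol")
}

# Planar benzene hexagon, alternating Kekule bond orders.
mk_benzene <- function(radius = 1.39) {
  th <- seq(0, by = pi / 3, length.out = 6)
  molecule(rep("C", 6), cbind(radius * cos(th), radius * sin(th), 0),
           data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(2, 1), 3)),
           name = "benzene")
}

# Para-dichlorobenzene: benzene with Cl on atoms 1 and 4 (along x).
mk_para_dichloro <- function() {
  b <- mk_benzene()
  xyz <- rbind(b$xyz, c(3.10, 0, 0), c(-3.10, 0, 0))
  bonds <- rbind(b$bonds, data.frame(i = c(1, 4), j = c(7, 8), order = 1))
  molecule(c(rep("C", 6), "Cl", "Cl"), xyz, bonds, name = "p-dichlorobenzene")
}

# PDB text for a CA-only chain with a given sequence along a helix-like
# spiral starting at `origin`.
mk_ca_chain_pdb <- function(seq1, chain = "A", origin = c(0, 0, 0)) {
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  res <- strsplit(seq1, "")[[1]]
  n <- length(res)
  t <- seq_len(n)
  xyz <- cbind(origin[1] + 2.3 * cos(t), origin[2] + 2.3 * sin(t),
               origin[3] + 1.5 * t)
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          t, aa3[res], chain, t, xyz[, 1], xyz[, 2], xyz[, 3])
}

mk_hetatm_lines <- function(xyz, elements, resname = "LIG", chain = "A",
                            resno = 900, start_serial = 5000) {
  sprintf("HETATM%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          start_serial + seq_len(nrow(xyz)) - 1,
          paste0(toupper(elements), seq_len(nrow(xyz))), resname, chain, resno,
          xyz[, 1], xyz[, 2], xyz[, 3], toupper(elements))
}

# Shared expensive fixtures, built once per test session.
.fixture_env <- new.env(parent = emptyenv())

shared_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

toylib_identical <- function() {
  shared_fixture("toylib_identical",
                 function() make_toy_library(2, "identical", seed = 101))
}

toylib_dissimilar <- function() {
  shared_fixture("toylib_dissimilar",
                 function() make_toy_library(3, "dissimilar-shared-mode",
                                             seed = 202))
}

clear_embed_cache <- function() {
  rm(list = ls(envir = templig:::.templig_cache),
     envir = templig:::.templig_cache)
}

# Independent brute-force minimum in-place RMSD over all element- and
# adjacency-preserving atom bijections (for molecules of equal composition,
# <= 12 heavy atoms). Used as the symmetry oracle for mcs_rmsd.
brute_force_symm_rmsd <- function(a, b) {
  a <- templig:::normalize_aromatic_orders(templig:::heavy_submol(a))
  b <- templig:::normalize_aromatic_orders(templig:::heavy_submol(b))
  n <- length(a$elements)
  stopifnot(n == length(b$elements), n <= 12)
  adj_a <- matrix(0, n, n); adj_b <- matrix(0, n, n)
  if (nrow(a$bonds)) {
    adj_a[cbind(a$bonds$i, a$bonds$j)] <- a$bonds$order
    adj_a[cbind(a$bonds$j, a$bonds$i)] <- a$bonds$order
  }
  if (nrow(b$bonds)) {
    adj_b[cbind(b$bonds$i, b$bonds$j)] <- b$bonds$order
    adj_b[cbind(b$bonds$j, b$bonds$i)] <- b$bonds$order
  }
  best <- Inf
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(k) {
    if (k > n) {
      d <- a$xyz - b$xyz[perm, , drop = FALSE]
      best <<- min(best, sqrt(mean(rowSums(d^2))))
      return(invisible())
    }
    for (cand in which(!used)) {
      if (a$elements[k] != b$elements[cand]) next
      ok <- TRUE
      for (prev in seq_len(k - 1)) {
        if (adj_a[k, prev] != adj_b[cand, perm[prev]]) { ok <- FALSE; break }
      }
      if (!ok) next
      perm[k] <<- cand; used[cand] <<- TRUE
      recurse(k + 1)
      used[cand] <<- FALSE
    }
  }
  recurse(1L)
  best
}
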