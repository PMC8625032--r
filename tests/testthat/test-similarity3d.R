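# Hybrid 3D similarity: pharmacophore perception, Gaussian shape overlap,
# the alignment optimizer, and 2D fingerprint Tanimoto.

test_that("feature perception follows the rule set", {
  f <- perceive_features(mk_methane())
  expect_equal(nrow(f), 1)
  expect_equal(f$kind, "hydrophobe")

  f <- perceive_features(mk_ethanol())
  expect_setequal(f$kind[f$kind != "hydrophobe"], c("donor", "acceptor"))
  # the hydroxyl oxygen carries both polar features
  oxy <- templig:::heavy_submol(mk_ethanol())$xyz[3, ]
  polar <- f[f$kind %in% c("donor", "acceptor"), ]
  expect_true(all(abs(as.matrix(polar[, c("x", "y", "z")]) -
                        matrix(oxy, 2, 3, byrow = TRUE)) < 1e-9))

  b <- mk_benzene()
  f <- perceive_features(b)
  arom <- f[f$kind == "aromatic", ]
  expect_equal(nrow(arom), 1)
  expect_equal(as.numeric(arom[1, c("x", "y", "z")]), colMeans(b$xyz),
               tolerance = 1e-9)
})

test_that("pairwise Gaussian overlap matches the closed-form two-atom integral", {
  p <- 2.7
  r_c <- 1.70
  alpha <- pi * (3 * p / (4 * pi * r_c^3))^(2 / 3)
  two_c <- function(d) {
    molecule(c("C"), matrix(c(d, 0, 0), 1, 3))
  }
  for (d in c(0, 0.7, 1.4, 2.9)) {
    got <- gaussian_shape_overlap(mk_methane(), two_c(d))
    want <- p^2 * (pi / (2 * alpha))^1.5 * exp(-alpha^2 * d^2 / (2 * alpha))
    expect_equal(got, want, tolerance = 1e-10)
  }
  # symmetry and the separation limit
  a <- mk_ethanol(); b <- mk_benzene()
  expect_equal(gaussian_shape_overlap(a, b), gaussian_shape_overlap(b, a))
  far <- b; far$xyz <- far$xyz + 100
  o_aa <- gaussian_shape_overlap(b, b)
  expect_lt(gaussian_shape_overlap(b, far), 1e-9 * o_aa)
})

test_that("self-alignment reaches the exact score endpoints", {
  for (m in list(mk_ethanol(), mk_benzene(), toy_ligand(1))) {
    al <- align(m, m)
    expect_equal(al$hybrid_sim, 2, tolerance = 1e-3)
    expect_equal(al$shape_score, 1, tolerance = 1e-3)
  }
})

test_that("alignment recovers a random rigid transform of the same molecule", {
  m <- toy_ligand(2)
  for (s in 1:3) {
    set.seed(s)
    tf <- rigid_transform(templig:::rotvec_to_mat(runif(3, -pi, pi)),
                          runif(3, -6, 6))
    moved <- templig:::transform_molecule(m, tf)
    al <- align(moved, m)
    expect_gte(al$hybrid_sim, 1.99)
    realigned <- templig:::transform_molecule(moved, al$transform)
    expect_lt(templig:::rmsd_xyz(heavy_xyz(realigned), heavy_xyz(m)), 1e-2)
  }
})

test_that("equal-shape hydrocarbon mimic scores high shape but zero feature", {
  glycol <- parse_smiles("OCCO")     # every heavy atom polar or O-adjacent
  butane <- parse_smiles("CCCC")     # pure hydrophobe feature set
  expect_true(all(perceive_features(glycol)$kind %in% c("donor", "acceptor")))
  expect_true(all(perceive_features(butane)$kind == "hydrophobe"))
  al <- align(glycol, butane)
  expect_gt(al$shape_score, 0.5)
  expect_equal(al$feature_score, 0)
})

test_that("scores stay in bounds and are rigid-invariant", {
  set.seed(7)
  mols <- lapply(c(1, 3, 16, 19), toy_ligand)
  for (k in 1:4) {
    a <- mols[[k]]; b <- mols[[(k %% 4) + 1]]
    al <- align(a, b)
    expect_gte(al$shape_score, 0); expect_lte(al$shape_score, 1)
    expect_gte(al$feature_score, 0); expect_lte(al$feature_score, 1)
    expect_equal(al$hybrid_sim, al$shape_score + al$feature_score,
                 tolerance = 1e-9)
    tf <- rigid_transform(templig:::rotvec_to_mat(runif(3, -1, 1)),
                          runif(3, -4, 4))
    al2 <- align(templig:::transform_molecule(a, tf),
                 templig:::transform_molecule(b, tf))
    expect_equal(al2$hybrid_sim, al$hybrid_sim, tolerance = 1e-3)
  }
})

test_that("optimizer beats a deterministic rotation/translation grid", {
  # coarse but exhaustive reference search on small molecules
  grid_best <- function(query, template) {
    qh <- heavy_xyz(query); th <- heavy_xyz(template)
    cq <- colMeans(qh); ct <- colMeans(th)
    best <- -Inf
    angles <- seq(0, 330, by = 30) * pi / 180
    shifts <- as.matrix(expand.grid(s1 = c(-0.5, 0, 0.5),
                                    s2 = c(-0.5, 0, 0.5),
                                    s3 = c(-0.5, 0, 0.5)))
    for (a1 in angles) for (a2 in seq(0, 150, by = 30) * pi / 180)
      for (a3 in angles) {
        R <- templig:::rotvec_to_mat(c(0, 0, a1)) %*%
          templig:::rotvec_to_mat(c(0, a2, 0)) %*%
          templig:::rotvec_to_mat(c(a3, 0, 0))
        base <- sweep(sweep(qh, 2, cq) %*% t(R), 2, -ct)
        for (s in seq_len(nrow(shifts))) {
          moved <- sweep(base, 2, -shifts[s, ])
          q2 <- query; q2$xyz[templig:::heavy_idx(query), ] <- moved
          sh <- gaussian_shape_overlap(q2, template) /
            max(gaussian_shape_overlap(query, query),
                gaussian_shape_overlap(template, template))
          if (sh > best) best <- sh
        }
      }
    best
  }
  q <- mk_ethanol()
  t <- templig:::transform_molecule(
    mk_ethanol(), rigid_transform(templig:::rotvec_to_mat(c(0.4, -0.8, 1.1)),
                                  c(2, -1, 3)))
  ref <- grid_best(q, t)
  al <- align(q, t)
  expect_gte(al$shape_score, ref - 0.02)
})

test_that("2D Tanimoto matches explicit path-set enumeration", {
  eth <- mk_ethanol()
  prop <- molecule(c("C", "C", "C", "O"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(3.6, 1.3, 0)),
                   data.frame(i = 1:3, j = 2:4, order = 1))
  # brute-force path keys: ethanol {C, O, C-C, C-O, C-C-O},
  # propanol adds {C-C-C, C-C-C-O}; intersection 5, union 7
  expect_equal(tanimoto2d(eth, prop), 5 / 7, tolerance = 1e-12)
  expect_equal(tanimoto2d(eth, eth), 1)
  expect_equal(tanimoto2d(mk_methane(),
                          molecule("O", matrix(0, 1, 3))), 0)
  expect_equal(tanimoto2d(eth, prop), tanimoto2d(prop, eth))
})

test_that("best_superimposition picks the planted best conformer with tie rule", {
  tmpl <- toy_ligand(5)
  cc <- generate_conformers(tmpl$smiles, max_count = 6L, seed = 4)
  # decoys clearly distinct from the template geometry, plus the template's
  # own geometry planted as the last conformer
  autos <- templig:::graph_automorphisms(cc$parent)
  hmap <- templig:::heavy_idx(cc$parent)
  decoys <- Filter(function(x) templig:::symm_fitted_rmsd(
    x[hmap, , drop = FALSE], tmpl$xyz[hmap, , drop = FALSE], autos) > 1.0,
    cc$conformers)
  planted <- c(decoys, list(tmpl$xyz))
  cs <- conformer_set(cc$parent, planted)
  best <- best_superimposition(cs, tmpl)
  expect_equal(best$query_conformer_index, length(planted))
  expect_gte(best$hybrid_sim, 1.99)
  # exact ties resolve to the lower conformer index
  cs2 <- conformer_set(cc$parent, list(cc$conformers[[1]], cc$conformers[[1]]))
  expect_equal(best_superimposition(cs2, tmpl)$query_conformer_index, 1L)
})
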